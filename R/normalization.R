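#' Pairwise distribution-similarity AUROC between samples
#'
#' For each unordered pair of samples, computes the AUROC of one sample's
#' non-missing values against the other's: the probability that a random
#' value from sample j exceeds a random value from sample i, ties counted
#' half (the Mann-Whitney rank construction -- exact and deterministic,
#' no fitted classifier). Two samples drawn from the same distribution
#' give AUROC 0.5; a location shift drives it towards 0 or 1. Each pair's
#' similarity is `1 - 2 * |AUROC - 0.5|` (1 = indistinguishable, 0 =
#' perfectly separable) and the table's `similarity_score` is the
#' unweighted mean over pairs, so a perfectly quantile-normalized table
#' scores exactly 1.
#'
#' @param table an [omics_data_table()].
#' @return list of class `distribution_similarity` with `table_name`,
#'   `pairwise_auroc` (samples x samples, diagonal 0.5, satisfying
#'   `A[i,j] + A[j,i] = 1`), `similarity_score`, and
#'   `per_sample_quartiles` (samples x c(Q1, median, Q3)).
#' @export
pairwise_distribution_auroc <- function(table) {
  vals <- lapply(seq_len(ncol(table$values)), function(j) {
    v <- table$values[, j]
    v[!is.na(v)]
  })
  names(vals) <- colnames(table$values)
  usable <- lengths(vals) >= 2L
  if (any(!usable)) {
    warning("excluding sample(s) with < 2 observations: ",
            paste(names(vals)[!usable], collapse = ", "))
    vals <- vals[usable]
  }
  n <- length(vals)
  if (n < 2L) stop("need >= 2 samples with >= 2 observations each")
  A <- matrix(0.5, n, n, dimnames = list(names(vals), names(vals)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- rank_auroc(pos = vals[[j]], neg = vals[[i]])
      A[i, j] <- a
      A[j, i] <- 1 - a
    }
  }
  sims <- 1 - 2 * abs(A[upper.tri(A)] - 0.5)
  q <- t(vapply(vals, quantile, numeric(3), probs = c(0.25, 0.5, 0.75),
                names = FALSE))
  colnames(q) <- c("Q1", "median", "Q3")
  structure(list(table_name = table$name,
                 pairwise_auroc = A,
                 similarity_score = mean(sims),
                 per_sample_quartiles = q),
            class = "distribution_similarity")
}

#' Per-sample abundance distribution summary
#'
#' Five-number summary (type-7 quantiles, i.e. linear interpolation
#' between order statistics) per sample plus kernel density estimates on
#' a grid shared across samples, whose bounds are the global minimum and
#' maximum of the non-missing values. This backs the boxplot/density
#' visualizations of the normalization section.
#'
#' @param table an [omics_data_table()].
#' @param n_grid number of density grid points.
#' @return list with `five_num` (samples x c(min, Q1, median, Q3, max))
#'   and `density` (list with `grid` and samples x grid matrix `y`).
#' @export
abundance_distribution_summary <- function(table, n_grid = 256L) {
  vals <- lapply(seq_len(ncol(table$values)), function(j) {
    v <- table$values[, j]
    v[!is.na(v)]
  })
  names(vals) <- colnames(table$values)
  usable <- lengths(vals) >= 2L
  if (any(!usable)) {
    warning("excluding empty/degenerate sample(s): ",
            paste(names(vals)[!usable], collapse = ", "))
    vals <- vals[usable]
  }
  if (!length(vals)) stop("no sample has >= 2 observations")
  five <- t(vapply(vals, quantile, numeric(5),
                   probs = c(0, 0.25, 0.5, 0.75, 1), names = FALSE))
  colnames(five) <- c("min", "Q1", "median", "Q3", "max")
  lo <- min(five[, "min"])
  hi <- max(five[, "max"])
  if (lo == hi) hi <- lo + 1  # constant table: degenerate but plottable
  dens <- t(vapply(vals, function(v) {
    if (var(v) == 0) {
      y <- numeric(n_grid)  # point mass: no bandwidth, flat zero curve
    } else {
      y <- density(v, from = lo, to = hi, n = n_grid)$y
    }
    y
  }, numeric(n_grid)))
  list(five_num = five,
       density = list(grid = seq(lo, hi, length.out = n_grid), y = dens))
}
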