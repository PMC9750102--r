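#' PCA embedding of samples
#'
#' Features with missing values are imputed by their median (embedding
#' only -- every other metric in the package works on pairwise-complete
#' data), zero-variance features dropped, values centered per feature,
#' and samples embedded by principal components. Each component's sign is
#' fixed so its largest-magnitude feature loading is positive, making the
#' embedding deterministic across platforms.
#'
#' @param table an [omics_data_table()] with >= 3 samples.
#' @param n_components maximum number of components to return.
#' @return list with `coords` (samples x components), `var_fraction`
#'   (per returned component, non-increasing) and `var_fraction_all`.
#' @export
pca_embed <- function(table, n_components = 10L) {
  X <- table$values
  if (ncol(X) < 3L) stop("PCA needs >= 3 samples")
  keep <- rowSums(!is.na(X)) > 0L
  X <- X[keep, , drop = FALSE]
  if (anyNA(X)) {
    med <- apply(X, 1L, median, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- med[idx[, 1L]]
  }
  v <- apply(X, 1L, var)
  X <- X[v > 0, , drop = FALSE]
  if (nrow(X) == 0L) {
    # all features constant: zero-variance embedding
    k <- min(n_components, ncol(table$values) - 1L)
    coords <- matrix(0, ncol(table$values), k,
                     dimnames = list(colnames(table$values),
                                     paste0("PC", seq_len(k))))
    return(list(coords = coords, var_fraction = rep(0, k),
                var_fraction_all = rep(0, k)))
  }
  pc <- prcomp(t(X), center = TRUE, scale. = FALSE)
  tot <- sum(pc$sdev^2)
  vf_all <- if (tot > 0) pc$sdev^2 / tot else rep(0, length(pc$sdev))
  k <- min(n_components, ncol(pc$x))
  coords <- pc$x[, seq_len(k), drop = FALSE]
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    flip <- rot[which.max(abs(rot[, j])), j]
    if (flip < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- colnames(table$values)
  list(coords = coords, var_fraction = vf_all[seq_len(k)],
       var_fraction_all = vf_all)
}

#' Average silhouette width of labelled points
#'
#' Standard silhouette on Euclidean distance over the supplied
#' coordinates: for each point, `a` is its mean distance to its own
#' cluster (excluding itself), `b` the smallest mean distance to any
#' other cluster, and `s = (b - a) / max(a, b)`. Points in singleton
#' clusters get `s = 0`. Returns the mean over points: near 1 when the
#' labels (here: batches) separate the data -- a strong batch effect --
#' and near 0 when labels are unrelated to structure.
#'
#' @param coords numeric matrix, one row per sample.
#' @param labels factor-like label per row (>= 2 levels).
#' @return scalar in `[-1, 1]`.
#' @export
average_silhouette_width <- function(coords, labels) {
  coords <- as.matrix(coords)
  labels <- as.character(labels)
  stopifnot(nrow(coords) == length(labels))
  lev <- unique(labels)
  if (length(lev) < 2L) stop("silhouette undefined for a single label level")
  D <- as.matrix(dist(coords))
  n <- nrow(D)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1L) { s[i] <- 0; next }  # singleton cluster
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(lev[lev != labels[i]], function(l) {
      mean(D[i, labels == l])
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Principal component regression of batch on PC scores
#'
#' For each of the leading components, the proportion of that
#' component's variance explained by the batch factor is the one-way
#' ANOVA R-squared (between-group sum of squares over total). The
#' components' R-squared values are then averaged weighted by the
#' variance fraction each component explains, giving an estimate of the
#' fraction of dominant variation attributable to batch.
#'
#' @param coords samples x components score matrix.
#' @param var_fraction variance fraction per component.
#' @param labels batch label per sample (>= 2 levels).
#' @param n_top number of leading components to use.
#' @return scalar in `[0, 1]`.
#' @export
principal_component_regression <- function(coords, var_fraction, labels,
                                           n_top = ncol(coords)) {
  coords <- as.matrix(coords)
  labels <- as.character(labels)
  stopifnot(nrow(coords) == length(labels),
            length(var_fraction) >= min(n_top, ncol(coords)))
  if (length(unique(labels)) < 2L) {
    stop("principal component regression needs >= 2 label levels")
  }
  k <- min(n_top, ncol(coords))
  r2 <- w <- numeric(0)
  for (j in seq_len(k)) {
    y <- coords[, j]
    sst <- sum((y - mean(y))^2)
    if (sst == 0) next  # zero-variance component excluded
    gm <- tapply(y, labels, mean)
    ssb <- sum(tapply(y, labels, length) * (gm - mean(y))^2)
    r2 <- c(r2, ssb / sst)
    w <- c(w, var_fraction[j])
  }
  if (!length(r2) || sum(w) == 0) return(0)
  sum(w * r2) / sum(w)
}

#' Sample-sample Pearson correlation matrix
#'
#' Pearson correlation between sample columns on pairwise-complete
#' observations. Pairs with fewer than 3 complete features are set to
#' `NA` with a warning.
#'
#' @param table an [omics_data_table()] with >= 2 samples.
#' @return symmetric samples x samples matrix.
#' @export
sample_correlation_matrix <- function(table) {
  X <- table$values
  if (ncol(X) < 2L) stop("need >= 2 samples")
  R <- suppressWarnings(cor(X, use = "pairwise.complete.obs"))
  ncomp <- crossprod(!is.na(X))
  low <- ncomp < 3L
  diag(low) <- FALSE
  if (any(low)) {
    warning(sum(low) / 2, " sample pair(s) have < 3 complete features; ",
            "correlation set to NA")
    R[low] <- NA_real_
  }
  diag(R) <- 1
  R
}

#' Full batch-effect assessment of one table
#'
#' Combines [pca_embed()], [average_silhouette_width()] on the leading
#' `n_pca_components` (batch labels, Euclidean distance in PC space),
#' [principal_component_regression()] over the leading components
#' covering >= 80% of variance (capped at 10), and
#' [sample_correlation_matrix()]. Higher `asw_batch` / `pcr_batch_r2`
#' mean stronger batch effect (worse quality). With a single batch both
#' metrics are `NA` (not computable, not zero).
#'
#' @param table an [omics_data_table()].
#' @param annotation aligned annotation `data.frame`.
#' @param config an [evaluation_config()].
#' @return list of class `batch_assessment`.
#' @export
batch_assessment <- function(table, annotation, config = evaluation_config()) {
  stopifnot(identical(annotation$sample, sample_ids(table)))
  emb <- pca_embed(table, n_components = max(10L, config$n_pca_components))
  batch <- annotation$batch
  if (length(unique(batch)) >= 2L) {
    k_sil <- min(config$n_pca_components, ncol(emb$coords))
    asw <- average_silhouette_width(emb$coords[, seq_len(k_sil), drop = FALSE],
                                    batch)
    cum <- cumsum(emb$var_fraction_all)
    n_top <- min(which(cum >= 0.8), 10L, ncol(emb$coords))
    pcr <- principal_component_regression(emb$coords, emb$var_fraction,
                                          batch, n_top = n_top)
  } else {
    warning("table '", table$name, "': single batch, batch metrics skipped")
    asw <- pcr <- NA_real_
  }
  structure(list(table_name = table$name,
                 asw_batch = asw,
                 pcr_batch_r2 = pcr,
                 pca_coords = emb$coords,
                 var_fraction = emb$var_fraction,
                 sample_correlation = sample_correlation_matrix(table)),
            class = "batch_assessment")
}
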