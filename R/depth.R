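#' Summarize data depth of a table
#'
#' Counts identified features (at least one non-missing value) and
#' quantifiable features (non-missing in at least
#' `quantifiable_min_fraction` of samples), the number of non-missing
#' features per sample, and the per-feature missing fraction.
#'
#' @param table an [omics_data_table()].
#' @param config an [evaluation_config()].
#' @return list of class `depth_summary` with elements `table_name`,
#'   `n_identified`, `n_quantifiable`, `per_sample_counts` (named integer
#'   vector) and `missing_fraction_per_feature` (named numeric vector).
#' @export
depth_summary <- function(table, config = evaluation_config()) {
  obs <- !is.na(table$values)
  miss_frac <- 1 - rowMeans(obs)
  structure(list(
    table_name = table$name,
    n_identified = sum(rowSums(obs) > 0L),
    n_quantifiable = sum(rowMeans(obs) >= config$quantifiable_min_fraction),
    per_sample_counts = colSums(obs),
    missing_fraction_per_feature = miss_frac
  ), class = "depth_summary")
}

#' Exclusive feature-overlap pattern counts across tables
#'
#' For every non-empty membership pattern over the tables, counts the
#' identified features showing exactly that pattern (UpSet semantics:
#' exclusive intersections). Overlap is computed on identified features
#' (>= 1 observation), so all-missing placeholder rows do not inflate it.
#' Counts over all patterns sum to the size of the union of identified
#' feature sets.
#'
#' @param tables list of at least two [omics_data_table()].
#' @return `data.frame` with one logical membership column per table plus
#'   `count`, sorted by decreasing count.
#' @export
feature_overlap_sets <- function(tables) {
  if (length(tables) < 2L) {
    stop("feature_overlap_sets() needs >= 2 tables; ",
         "use depth_summary() for a single table")
  }
  nm <- vapply(tables, function(t) t$name, character(1))
  sets <- lapply(tables, identified_features)
  univ <- unique(unlist(sets))
  member <- vapply(sets, function(s) univ %in% s,
                   logical(length(univ)))
  member <- matrix(member, nrow = length(univ), dimnames = list(NULL, nm))
  key <- apply(member, 1L, function(r) paste(as.integer(r), collapse = ""))
  counts <- table(key)
  pat <- do.call(rbind, lapply(names(counts), function(k) {
    strsplit(k, "", fixed = TRUE)[[1L]] == "1"
  }))
  out <- as.data.frame(pat)
  names(out) <- nm
  out$count <- as.integer(counts)
  out[order(-out$count), , drop = FALSE]
}

#' Histogram of per-feature missing fractions
#'
#' Bins the per-feature missing-value fractions over `[0, 1]` into
#' `n_bins` right-closed bins (the first bin also includes 0). Bin counts
#' sum to the number of features.
#'
#' @param table an [omics_data_table()].
#' @param n_bins number of bins (>= 1).
#' @return `data.frame` with `bin_low`, `bin_high`, `count`.
#' @export
missing_value_histogram <- function(table, n_bins = 10L) {
  stopifnot(n_bins >= 1L)
  frac <- 1 - rowMeans(!is.na(table$values))
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  idx <- findInterval(frac, breaks, left.open = TRUE, rightmost.closed = TRUE)
  idx[idx == 0L] <- 1L  # frac == 0 goes in the first bin
  data.frame(bin_low = breaks[-length(breaks)],
             bin_high = breaks[-1L],
             count = tabulate(idx, nbins = n_bins))
}
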