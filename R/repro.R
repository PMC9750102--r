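#' QC-replicate coefficient of variation
#'
#' Computes, for each feature, the coefficient of variation (sample SD
#' with the n-1 denominator, divided by the mean) across the replicated
#' QC samples, on the linear scale: tables declared log2 are
#' back-transformed with `log_base_for_cv` first, since CV of log
#' intensities is not the conventional reproducibility measure. The
#' summary metric is the fraction of features with CV below
#' `cv_threshold` (default 0.30, i.e. the percentage of features with CV
#' less than 30%). Features with fewer than 2 QC observations or a
#' non-positive mean have no defined CV and are excluded (counted in
#' `n_excluded`).
#'
#' @param table an [omics_data_table()].
#' @param annotation aligned annotation `data.frame`; needs >= 2 rows
#'   with `is_qc = TRUE`.
#' @param config an [evaluation_config()].
#' @return list of class `cv_result` with `per_feature_cv`,
#'   `fraction_below_threshold`, `threshold`, `n_excluded`.
#' @export
qc_cv <- function(table, annotation, config = evaluation_config()) {
  stopifnot(identical(annotation$sample, sample_ids(table)))
  qc <- annotation$sample[annotation$is_qc]
  if (length(qc) < 2L) {
    stop("platform reproducibility skipped: < 2 QC replicate samples")
  }
  X <- table$values[, qc, drop = FALSE]
  if (table$scale == "log2") X <- config$log_base_for_cv^X
  m <- rowMeans(X, na.rm = TRUE)
  nobs <- rowSums(!is.na(X))
  s <- apply(X, 1L, sd, na.rm = TRUE)
  cv <- ifelse(nobs >= 2L & !is.na(m) & m > 0, s / m, NA_real_)
  names(cv) <- rownames(X)
  defined <- cv[!is.na(cv)]
  structure(list(table_name = table$name,
                 per_feature_cv = defined,
                 fraction_below_threshold =
                   if (length(defined)) mean(defined < config$cv_threshold)
                   else NA_real_,
                 threshold = config$cv_threshold,
                 n_excluded = sum(is.na(cv))),
            class = "cv_result")
}

#' Gene-wise and sample-wise paired-omics concordance
#'
#' For a table and its paired table from another omics layer (e.g.
#' protein and mRNA for the same cohort), computes per shared feature
#' the Spearman correlation across shared samples, and per shared sample
#' the Spearman correlation across shared features. Spearman is used
#' because cross-omics relationships are monotone but rarely linear.
#' Correlations are computed on complete pairs only and require at least
#' 6 of them; undefined entries are `NA`. Higher overall correlation
#' indicates better concordance, summarized as `median_genewise_r`.
#'
#' @param table an [omics_data_table()].
#' @param paired an [omics_data_table()] from the paired omics layer.
#' @param min_shared_features,min_shared_samples minimum overlap required.
#' @return list of class `concordance_result` with `genewise_r`,
#'   `samplewise_r`, `median_genewise_r`.
#' @export
paired_omics_concordance <- function(table, paired,
                                     min_shared_features = 10L,
                                     min_shared_samples = 6L) {
  feats <- intersect(feature_ids(table), feature_ids(paired))
  samps <- intersect(sample_ids(table), sample_ids(paired))
  if (length(feats) < min_shared_features ||
      length(samps) < min_shared_samples) {
    stop("insufficient overlap between '", table$name, "' and '",
         paired$name, "': ", length(feats), " shared features, ",
         length(samps), " shared samples")
  }
  A <- table$values[feats, samps, drop = FALSE]
  B <- paired$values[feats, samps, drop = FALSE]
  spearman_min6 <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 6L) return(NA_real_)
    suppressWarnings(cor(x[ok], y[ok], method = "spearman"))
  }
  genewise <- vapply(seq_along(feats), function(i) {
    spearman_min6(A[i, ], B[i, ])
  }, numeric(1))
  names(genewise) <- feats
  samplewise <- vapply(seq_along(samps), function(j) {
    spearman_min6(A[, j], B[, j])
  }, numeric(1))
  names(samplewise) <- samps
  structure(list(table_name = table$name,
                 genewise_r = genewise,
                 samplewise_r = samplewise,
                 median_genewise_r = median(genewise, na.rm = TRUE)),
            class = "concordance_result")
}
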