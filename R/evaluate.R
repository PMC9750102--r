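#' Evaluate one or more data tables on all quality axes
#'
#' The single wrapper around the whole pipeline: aligns the tables and
#' annotation onto their common samples, then computes per table the
#' depth summary, distribution-similarity AUROC, batch assessment
#' (silhouette + principal component regression + PCA + correlation
#' heatmap data), the biological-signal metrics (complex-pair
#' correlations, co-expression network pathway prediction, class
#' prediction, clustering concordance), the QC-replicate CV and the
#' paired-omics concordance. Groups whose inputs are absent (no QC
#' replicates, no gene sets, a single batch, not exactly two classes)
#' are skipped with a message and reported as absent, never as zero.
#'
#' @param tables list of [omics_data_table()].
#' @param annotation annotation `data.frame` from
#'   [read_sample_annotation()].
#' @param config an [evaluation_config()].
#' @param complexes,pathways optional `gene_set_collection`s.
#' @param paired optional paired-omics [omics_data_table()].
#' @return list of class `evaluation_report` with `results` (one list
#'   per table), `overlap`, `scores` (radar scores, see
#'   [normalize_scores()]), `annotation`, `config`.
#' @export
evaluate_tables <- function(tables, annotation,
                            config = evaluation_config(),
                            complexes = NULL, pathways = NULL,
                            paired = NULL) {
  al <- align_tables(tables, annotation)
  tables <- al$tables
  ann <- al$annotation
  try_group <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      message("skipping ", label, ": ", conditionMessage(e))
      NULL
    })
  }
  results <- lapply(tables, function(tab) {
    res <- list(
      depth = depth_summary(tab, config),
      distribution = pairwise_distribution_auroc(tab),
      abundance = abundance_distribution_summary(tab),
      missing_histogram = missing_value_histogram(tab),
      batch = suppressWarnings(batch_assessment(tab, ann, config))
    )
    res$complex <- if (!is.null(complexes)) {
      try_group(paste0("complex correlations [", tab$name, "]"),
                complex_pair_correlations(tab, complexes,
                                          n_pairs = config$n_complex_pairs,
                                          seed = config$random_seed))
    }
    res$function_prediction <- if (!is.null(pathways)) {
      try_group(paste0("function prediction [", tab$name, "]"), {
        net <- build_coexpression_network(tab, config)
        function_prediction_auroc(net, pathways, config)
      })
    }
    res$class_prediction <-
      try_group(paste0("class prediction [", tab$name, "]"),
                class_prediction_cv_auroc(tab, ann, config))
    res$clustering <-
      try_group(paste0("clustering [", tab$name, "]"),
                clustering_concordance(tab, ann))
    res$cv <- try_group(paste0("QC CV [", tab$name, "]"),
                        qc_cv(tab, ann, config))
    res$concordance <- if (!is.null(paired)) {
      try_group(paste0("paired-omics concordance [", tab$name, "]"),
                paired_omics_concordance(tab, paired))
    }
    res
  })
  names(results) <- vapply(tables, function(t) t$name, character(1))
  report <- structure(list(results = results,
                           overlap = if (length(tables) >= 2L)
                             feature_overlap_sets(tables) else NULL,
                           annotation = ann,
                           config = config),
                      class = "evaluation_report")
  report$scores <- normalize_scores(report)
  report
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report:", length(x$results), "table(s),",
      nrow(x$annotation), "samples\n")
  print(x$scores$scores, digits = 3)
  invisible(x)
}
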