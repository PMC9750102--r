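#' Normalize metric results into radar scores
#'
#' Maps each metric group onto a quality score in `[0, 1]` (higher =
#' better) with a fixed, documented transformation, recorded in
#' `mapping_record` so comparisons stay auditable:
#' \itemize{
#'   \item depth: `n_quantifiable / max(n_quantifiable over tables)`;
#'   \item normalization: the distribution `similarity_score`;
#'   \item batch: mean of `1 - clamp(asw_batch, 0, 1)` and
#'     `1 - pcr_batch_r2` (batch metrics measure badness, so they are
#'     inverted);
#'   \item signal: mean of the available AUROCs (complex separation,
#'     median pathway prediction, class prediction), each rescaled from
#'     `[0.5, 1]` to `[0, 1]` with clamping (0.5 = chance = no signal);
#'   \item reproducibility: `fraction_below_threshold` of QC CVs;
#'   \item concordance: `clamp(median_genewise_r, 0, 1)`.
#' }
#' Groups that were skipped are `NA` (absent), never zero.
#'
#' @param report an `evaluation_report` (scores slot may be unset).
#' @return list of class `radar_scores` with `scores` (tables x groups
#'   matrix) and `mapping_record`.
#' @export
normalize_scores <- function(report) {
  clamp01 <- function(x) pmin(1, pmax(0, x))
  rescale_auroc <- function(x) clamp01((x - 0.5) / 0.5)
  nq <- vapply(report$results, function(r) r$depth$n_quantifiable,
               numeric(1))
  groups <- c("depth", "normalization", "batch", "signal",
              "reproducibility", "concordance")
  S <- matrix(NA_real_, length(report$results), length(groups),
              dimnames = list(names(report$results), groups))
  for (nm in names(report$results)) {
    r <- report$results[[nm]]
    S[nm, "depth"] <- if (max(nq) > 0) r$depth$n_quantifiable / max(nq)
                      else NA_real_
    S[nm, "normalization"] <- r$distribution$similarity_score
    if (!is.null(r$batch) && !is.na(r$batch$asw_batch)) {
      S[nm, "batch"] <- mean(c(1 - clamp01(r$batch$asw_batch),
                               1 - clamp01(r$batch$pcr_batch_r2)))
    }
    sig <- c(if (!is.null(r$complex)) r$complex$separation_auroc,
             if (!is.null(r$function_prediction))
               r$function_prediction$median_auroc,
             if (!is.null(r$class_prediction))
               r$class_prediction$cv_auroc)
    sig <- sig[!is.na(sig)]
    if (length(sig)) S[nm, "signal"] <- mean(rescale_auroc(sig))
    if (!is.null(r$cv)) {
      S[nm, "reproducibility"] <- r$cv$fraction_below_threshold
    }
    if (!is.null(r$concordance)) {
      S[nm, "concordance"] <- clamp01(r$concordance$median_genewise_r)
    }
  }
  structure(list(
    scores = S,
    mapping_record = c(
      depth = "n_quantifiable / max over tables",
      normalization = "mean over sample pairs of 1 - 2|AUROC - 0.5|",
      batch = "mean of 1 - clamp(asw, 0, 1) and 1 - pcr_r2",
      signal = "mean of available AUROCs rescaled [0.5,1] -> [0,1]",
      reproducibility = "fraction of QC CVs below threshold",
      concordance = "clamp(median gene-wise Spearman r, 0, 1)")),
    class = "radar_scores")
}

#' Render the evaluation report
#'
#' Writes every figure's underlying numbers as TSV files (the single
#' source of truth -- the HTML shows the same values), renders static
#' PNG figures, and assembles one self-contained HTML report with an
#' introduction (tables and sample summary), an overview (score table +
#' radar plot) and one section per metric group. Given the same
#' `evaluation_report`, output TSVs are byte-identical across runs.
#'
#' @param report an `evaluation_report` from [evaluate_tables()].
#' @param out_dir output directory (created if needed).
#' @return path of the HTML file, invisibly.
#' @export
render_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out_dir, mode = 2) != 0) {
    stop("output directory '", out_dir, "' is not writable")
  }
  tsv <- function(df, name) {
    path <- file.path(out_dir, name)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) format_num(x))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA")
    path
  }
  res <- report$results
  nm <- names(res)

  ## ---- persist all numbers first -------------------------------------
  tsv(data.frame(table = nm,
                 n_identified = vapply(res, function(r)
                   r$depth$n_identified, numeric(1)),
                 n_quantifiable = vapply(res, function(r)
                   r$depth$n_quantifiable, numeric(1))),
      "depth_summary.tsv")
  for (t in nm) {
    d <- res[[t]]$depth
    tsv(data.frame(sample = names(d$per_sample_counts),
                   n_features = as.integer(d$per_sample_counts)),
        paste0("per_sample_counts_", t, ".tsv"))
    tsv(res[[t]]$missing_histogram, paste0("missing_histogram_", t, ".tsv"))
    A <- res[[t]]$distribution$pairwise_auroc
    tsv(data.frame(sample = rownames(A), as.data.frame(A),
                   check.names = FALSE),
        paste0("distribution_auroc_", t, ".tsv"))
    b <- res[[t]]$batch
    tsv(data.frame(sample = rownames(b$pca_coords),
                   as.data.frame(b$pca_coords), check.names = FALSE),
        paste0("pca_coords_", t, ".tsv"))
    tsv(data.frame(sample = rownames(b$sample_correlation),
                   as.data.frame(b$sample_correlation),
                   check.names = FALSE),
        paste0("sample_correlation_", t, ".tsv"))
    if (!is.null(res[[t]]$complex)) {
      cc <- res[[t]]$complex
      tsv(data.frame(group = rep(c("intra", "inter"),
                                 each = length(cc$intra_correlations)),
                     r = c(cc$intra_correlations, cc$inter_correlations)),
          paste0("complex_pairs_", t, ".tsv"))
    }
    if (!is.null(res[[t]]$function_prediction) &&
        length(res[[t]]$function_prediction$per_pathway_auroc)) {
      fp <- res[[t]]$function_prediction
      tsv(data.frame(pathway = names(fp$per_pathway_auroc),
                     auroc = as.numeric(fp$per_pathway_auroc)),
          paste0("pathway_auroc_", t, ".tsv"))
    }
    if (!is.null(res[[t]]$cv)) {
      tsv(data.frame(feature = names(res[[t]]$cv$per_feature_cv),
                     cv = as.numeric(res[[t]]$cv$per_feature_cv)),
          paste0("qc_cv_", t, ".tsv"))
    }
    if (!is.null(res[[t]]$concordance)) {
      co <- res[[t]]$concordance
      tsv(data.frame(feature = names(co$genewise_r),
                     spearman_r = as.numeric(co$genewise_r)),
          paste0("concordance_genewise_", t, ".tsv"))
      tsv(data.frame(sample = names(co$samplewise_r),
                     spearman_r = as.numeric(co$samplewise_r)),
          paste0("concordance_samplewise_", t, ".tsv"))
    }
  }
  if (!is.null(report$overlap)) tsv(report$overlap, "overlap_patterns.tsv")
  metric_row <- function(r) {
    c(similarity_score = r$distribution$similarity_score,
      asw_batch = if (is.null(r$batch)) NA else r$batch$asw_batch,
      pcr_batch_r2 = if (is.null(r$batch)) NA else r$batch$pcr_batch_r2,
      complex_separation_auroc =
        if (is.null(r$complex)) NA else r$complex$separation_auroc,
      function_median_auroc = if (is.null(r$function_prediction)) NA
        else r$function_prediction$median_auroc,
      class_cv_auroc = if (is.null(r$class_prediction)) NA
        else r$class_prediction$cv_auroc,
      ari_vs_class = if (is.null(r$clustering)) NA
        else r$clustering$ari_vs_class,
      ari_vs_batch = if (is.null(r$clustering)) NA
        else r$clustering$ari_vs_batch,
      cv_fraction_below_threshold = if (is.null(r$cv)) NA
        else r$cv$fraction_below_threshold,
      median_genewise_r = if (is.null(r$concordance)) NA
        else r$concordance$median_genewise_r)
  }
  metrics <- t(vapply(res, metric_row, numeric(10)))
  tsv(data.frame(table = nm, as.data.frame(metrics), check.names = FALSE),
      "metric_summary.tsv")
  S <- report$scores$scores
  tsv(data.frame(table = rownames(S), as.data.frame(S),
                 check.names = FALSE), "scores.tsv")

  ## ---- figures --------------------------------------------------------
  figs <- character(0)
  fig <- function(name, width, height, code) {
    path <- file.path(out_dir, name)
    grDevices::png(path, width = width, height = height, res = 96)
    ok <- tryCatch({ code(); TRUE },
                   error = function(e) FALSE)
    grDevices::dev.off()
    if (ok) figs[[name]] <<- path else unlink(path)
  }
  fig("radar.png", 640, 560, function() radar_plot(S))
  fig("pca.png", 360 * length(nm), 380, function() {
    op <- par(mfrow = c(1, length(nm)), mar = c(4, 4, 3, 1))
    on.exit(par(op))
    for (t in nm) {
      b <- res[[t]]$batch
      bt <- factor(report$annotation$batch)
      plot(b$pca_coords[, 1], b$pca_coords[, 2], col = as.integer(bt),
           pch = 19, main = t,
           xlab = sprintf("PC1 (%.1f%%)", 100 * b$var_fraction[1]),
           ylab = sprintf("PC2 (%.1f%%)", 100 * b$var_fraction[2]))
      legend("topright", legend = levels(bt), col = seq_along(levels(bt)),
             pch = 19, cex = 0.8)
    }
  })
  fig("per_sample_counts.png", 640, 380, function() {
    op <- par(mar = c(4, 4, 2, 1))
    on.exit(par(op))
    cnts <- lapply(res, function(r) as.numeric(r$depth$per_sample_counts))
    ord <- order(report$annotation$order)
    plot(NA, xlim = c(1, nrow(report$annotation)),
         ylim = range(unlist(cnts)), xlab = "run order",
         ylab = "features identified", main = "Features per sample")
    for (i in seq_along(cnts)) {
      points(seq_along(ord), cnts[[i]][ord], col = i, pch = 19)
    }
    legend("bottomright", legend = nm, col = seq_along(nm), pch = 19,
           cex = 0.8)
  })
  fig("abundance_boxplot.png", 640, 380, function() {
    op <- par(mfrow = c(1, length(nm)), mar = c(4, 4, 3, 1))
    on.exit(par(op))
    for (t in nm) {
      f <- res[[t]]$abundance$five_num
      boxplot(t(f[, c("min", "Q1", "median", "Q3", "max")]),
              names = NULL, xaxt = "n", main = t, ylab = "abundance",
              xlab = "samples")
    }
  })
  fig("qc_cv.png", 640, 380, function() {
    cvs <- lapply(res, function(r) if (is.null(r$cv)) NULL
                  else as.numeric(r$cv$per_feature_cv))
    cvs <- cvs[!vapply(cvs, is.null, logical(1))]
    if (!length(cvs)) stop("no CV data")
    op <- par(mar = c(4, 4, 2, 1))
    on.exit(par(op))
    hist(cvs[[1]], breaks = 30, col = "grey80", border = "white",
         xlab = "QC coefficient of variation", main = "QC CV distribution")
    abline(v = res[[1]]$cv$threshold, col = 2, lty = 2)
  })

  ## ---- HTML ------------------------------------------------------------
  html <- file.path(out_dir, "report.html")
  writeLines(build_html(report, metrics, figs), html)
  invisible(html)
}

# Minimal radar (spider) chart over metric-group scores, one polygon per
# table; absent (NA) groups are left out of that table's polygon.
radar_plot <- function(S) {
  g <- ncol(S)
  ang <- pi / 2 - 2 * pi * (seq_len(g) - 1) / g
  op <- par(mar = c(1, 1, 2, 1))
  on.exit(par(op))
  plot(NA, xlim = c(-1.5, 1.5), ylim = c(-1.4, 1.4), axes = FALSE,
       xlab = "", ylab = "", main = "Quality overview", asp = 1)
  for (r in c(0.25, 0.5, 0.75, 1)) {
    polygon(r * cos(ang), r * sin(ang), border = "grey80")
  }
  for (j in seq_len(g)) {
    lines(c(0, cos(ang[j])), c(0, sin(ang[j])), col = "grey80")
    text(1.22 * cos(ang[j]), 1.22 * sin(ang[j]), colnames(S)[j],
         cex = 0.85)
  }
  for (i in seq_len(nrow(S))) {
    v <- as.numeric(S[i, ])
    ok <- !is.na(v)
    polygon((v * cos(ang))[ok], (v * sin(ang))[ok],
            border = i + 1, col = grDevices::adjustcolor(i + 1, 0.15),
            lwd = 2)
  }
  legend("bottomleft", legend = rownames(S), col = seq_len(nrow(S)) + 1,
         lwd = 2, cex = 0.85, bty = "n")
}

html_table <- function(df, digits = 3) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = digits,
                                                 format = "g"))
  head_row <- paste0("<tr>", paste0("<th>", names(df), "</th>",
                                    collapse = ""), "</tr>")
  body <- apply(df, 1L, function(r) {
    paste0("<tr>", paste0("<td>", r, "</td>", collapse = ""), "</tr>")
  })
  paste0("<table>", head_row, paste(body, collapse = ""), "</table>")
}

embed_png <- function(path, alt = "") {
  if (is.null(path) || !file.exists(path)) return("")
  b64 <- jsonlite::base64_enc(readBin(path, "raw", file.size(path)))
  paste0("<img alt=\"", alt, "\" src=\"data:image/png;base64,",
         gsub("\n", "", b64), "\"/>")
}

build_html <- function(report, metrics, figs) {
  res <- report$results
  nm <- names(res)
  ann <- report$annotation
  sec <- function(title, ...) {
    c(paste0("<h2>", title, "</h2>"), ...)
  }
  skipped <- function(label) {
    paste0("<p class=\"skip\">", label,
           " was skipped for this run (required inputs absent).</p>")
  }
  S <- report$scores$scores
  lines <- c(
    "<!DOCTYPE html><html><head><meta charset=\"utf-8\"/>",
    "<title>Omics data table quality evaluation</title>",
    "<style>body{font-family:sans-serif;max-width:1000px;margin:auto}",
    "table{border-collapse:collapse;margin:8px 0}",
    "td,th{border:1px solid #999;padding:3px 8px;text-align:right}",
    "th{background:#eee}.skip{color:#a40}img{max-width:100%}</style>",
    "</head><body>",
    "<h1>Omics data table quality evaluation</h1>",
    sec("Introduction",
        paste0("<p>", length(nm), " data table(s) evaluated over ",
               nrow(ann), " aligned samples (",
               sum(!ann$is_qc), " study samples, ", sum(ann$is_qc),
               " QC replicates; ", length(unique(ann$batch)),
               " batch(es); classes: ",
               paste(sort(unique(ann$class[!ann$is_qc])), collapse = ", "),
               ").</p>"),
        html_table(data.frame(
          table = nm,
          features = vapply(res, function(r)
            length(r$depth$missing_fraction_per_feature), numeric(1)),
          identified = vapply(res, function(r) r$depth$n_identified,
                              numeric(1)),
          quantifiable = vapply(res, function(r) r$depth$n_quantifiable,
                                numeric(1))))),
    sec("Overview",
        html_table(data.frame(table = rownames(S), as.data.frame(S),
                              check.names = FALSE)),
        html_table(data.frame(table = nm, as.data.frame(metrics),
                              check.names = FALSE)),
        embed_png(figs[["radar.png"]], "radar plot of quality scores")),
    sec("Group 1 &mdash; data depth",
        embed_png(figs[["per_sample_counts.png"]], "features identified per sample"),
        if (!is.null(report$overlap))
          html_table(report$overlap) else
          "<p>Feature overlap needs at least two tables.</p>"),
    sec("Group 2 &mdash; normalization",
        html_table(data.frame(table = nm,
                              similarity_score = metrics[, "similarity_score"])),
        embed_png(figs[["abundance_boxplot.png"]], "abundance distributions")),
    sec("Group 3 &mdash; batch effect",
        html_table(data.frame(table = nm,
                              asw_batch = metrics[, "asw_batch"],
                              pcr_batch_r2 = metrics[, "pcr_batch_r2"])),
        embed_png(figs[["pca.png"]], "PCA colored by batch")),
    sec("Group 4 &mdash; biological signal",
        html_table(data.frame(
          table = nm,
          complex_separation_auroc = metrics[, "complex_separation_auroc"],
          function_median_auroc = metrics[, "function_median_auroc"],
          class_cv_auroc = metrics[, "class_cv_auroc"],
          ari_vs_class = metrics[, "ari_vs_class"],
          ari_vs_batch = metrics[, "ari_vs_batch"]))),
    sec("Group 5 &mdash; platform reproducibility",
        if (all(is.na(metrics[, "cv_fraction_below_threshold"])))
          skipped("QC-replicate CV analysis") else
          c(html_table(data.frame(
              table = nm,
              cv_fraction_below_threshold =
                metrics[, "cv_fraction_below_threshold"])),
            embed_png(figs[["qc_cv.png"]], "QC CV distribution"))),
    sec("Group 6 &mdash; multi-omics concordance",
        if (all(is.na(metrics[, "median_genewise_r"])))
          skipped("Paired-omics concordance") else
          html_table(data.frame(
            table = nm,
            median_genewise_r = metrics[, "median_genewise_r"]))),
    "</body></html>")
  unlist(lines)
}
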