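#' Specify a synthetic evaluation fixture
#'
#' Describes a synthetic study with controllable depth, batch shift,
#' co-expression module structure, class effect, missingness and QC
#' replicates, from which [generate_fixture()] produces every input the
#' evaluation pipeline needs. Values are on the log2 scale. Module
#' features share a per-sample latent factor, so the expected
#' intra-module Pearson correlation has the closed form
#' `module_latent_sd^2 / (module_latent_sd^2 + noise_sd^2)` while
#' between-module correlations are near zero.
#'
#' @param n_features,n_samples,n_batches study dimensions (`n_samples`
#'   counts study samples; QC replicates come on top).
#' @param batch_shift additive log2 shift applied to every feature of
#'   samples in non-reference batches (0 = no batch effect).
#' @param n_modules,module_size co-expression module structure;
#'   `n_modules * module_size <= n_features`.
#' @param module_latent_sd,noise_sd SD of the per-sample module latent
#'   factor and of the i.i.d. measurement noise, log2 units.
#' @param missing_rate completely-at-random missingness fraction.
#' @param n_qc number of QC replicates (noisy copies of a pooled
#'   reference sample).
#' @param class_effect_sd additive log2 class effect applied to the
#'   first 20 features for the second class level.
#' @param seed RNG seed; identical specs generate byte-identical output.
#' @return a list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_features = 300L, n_samples = 60L,
                         n_batches = 2L, batch_shift = 0,
                         n_modules = 5L, module_size = 20L,
                         module_latent_sd = 1, noise_sd = 0.5,
                         missing_rate = 0.05, n_qc = 5L,
                         class_effect_sd = 1, seed = 1L) {
  stopifnot(n_features >= 1, n_samples >= 4, n_batches >= 1,
            n_modules >= 0, module_size >= 2 || n_modules == 0,
            n_modules * module_size <= n_features,
            module_latent_sd > 0, noise_sd > 0,
            missing_rate >= 0, missing_rate < 1,
            n_qc >= 0, batch_shift >= 0, class_effect_sd >= 0)
  structure(list(n_features = as.integer(n_features),
                 n_samples = as.integer(n_samples),
                 n_batches = as.integer(n_batches),
                 batch_shift = batch_shift,
                 n_modules = as.integer(n_modules),
                 module_size = as.integer(module_size),
                 module_latent_sd = module_latent_sd,
                 noise_sd = noise_sd,
                 missing_rate = missing_rate,
                 n_qc = as.integer(n_qc),
                 class_effect_sd = class_effect_sd,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic evaluation fixture
#'
#' Builds, fully reproducibly from `spec$seed`: a log2-scale data table
#' (module features = per-sample latent factor + noise, background
#' features i.i.d. noise around a feature baseline, batch shift on
#' non-reference batches, class effect on the first 20 features for
#' class "B", MCAR missingness), a sample annotation with two classes,
#' batches, run order and QC flags, complex and pathway gene-set
#' collections equal to the modules, and a paired-omics table = table +
#' independent noise. If `dir` is given everything is also written in
#' the package's TSV/GMT dialects.
#'
#' @param spec a [fixture_spec()].
#' @param dir optional output directory (created if needed); tables go
#'   to `dir/tables/`, annotation to `dir/sample_annotation.tsv`, gene
#'   sets to `dir/complexes.gmt` / `dir/pathways.gmt`, the paired table
#'   to `dir/paired.tsv`.
#' @return list with `table` (an [omics_data_table()] named "clean"),
#'   `annotation`, `complexes`, `pathways`, `paired`, and `paths` when
#'   `dir` was given.
#' @export
generate_fixture <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  p <- spec$n_features
  n <- spec$n_samples
  feats <- sprintf("f%04d", seq_len(p))
  samp <- sprintf("s%03d", seq_len(n + spec$n_qc))
  cls <- c(rep(c("A", "B"), c(ceiling(n / 2), floor(n / 2))),
           rep("QC", spec$n_qc))
  batch <- paste0("B", rep_len(seq_len(spec$n_batches), n + spec$n_qc))
  is_qc <- c(rep(FALSE, n), rep(TRUE, spec$n_qc))
  ann <- data.frame(sample = samp, class = cls, batch = batch,
                    order = seq_along(samp), is_qc = is_qc,
                    stringsAsFactors = FALSE)
  # modules occupy the tail of the feature vector so the class-effect
  # features (head) stay independent of the module latent factors
  module_of <- rep(NA_integer_, p)
  if (spec$n_modules > 0) {
    n_mod <- spec$n_modules * spec$module_size
    module_of[(p - n_mod + 1L):p] <-
      rep(seq_len(spec$n_modules), each = spec$module_size)
  }
  with_seed(spec$seed, {
    baseline <- rnorm(p, mean = 20, sd = 2)
    X <- matrix(rnorm(p * length(samp), sd = spec$noise_sd), p,
                dimnames = list(feats, samp))
    X <- X + baseline
    if (spec$n_modules > 0) {
      L <- matrix(rnorm(spec$n_modules * n, sd = spec$module_latent_sd),
                  spec$n_modules, n)
      for (m in seq_len(spec$n_modules)) {
        rows <- which(module_of == m)
        X[rows, seq_len(n)] <- X[rows, seq_len(n)] +
          rep(L[m, ], each = length(rows))
      }
    }
    k_eff <- min(20L, p)
    X[seq_len(k_eff), cls == "B"] <- X[seq_len(k_eff), cls == "B"] +
      spec$class_effect_sd
    if (spec$batch_shift != 0) {
      shifted <- batch != "B1"
      X[, shifted] <- X[, shifted] + spec$batch_shift
    }
    paired_vals <- X[, seq_len(n), drop = FALSE] +
      rnorm(p * n, sd = spec$noise_sd)
    if (spec$missing_rate > 0) {
      X[runif(length(X)) < spec$missing_rate] <- NA_real_
      paired_vals[runif(length(paired_vals)) < spec$missing_rate] <-
        NA_real_
    }
  })
  tab <- omics_data_table(X, "clean", scale = "log2")
  paired <- omics_data_table(paired_vals, "paired_mrna", scale = "log2")
  make_sets <- function(kind, prefix) {
    if (spec$n_modules == 0) return(gene_set_collection(list(), kind))
    sets <- lapply(seq_len(spec$n_modules), function(m) {
      feats[which(module_of == m)]
    })
    names(sets) <- paste0(prefix, seq_len(spec$n_modules))
    gene_set_collection(sets, kind)
  }
  complexes <- make_sets("complex", "complex_")
  pathways <- make_sets("pathway", "pathway_")
  out <- list(table = tab, annotation = ann, complexes = complexes,
              pathways = pathways, paired = paired)
  if (!is.null(dir)) {
    dir.create(file.path(dir, "tables"), recursive = TRUE,
               showWarnings = FALSE)
    paths <- list(
      table = file.path(dir, "tables", "clean.tsv"),
      annotation = file.path(dir, "sample_annotation.tsv"),
      complexes = file.path(dir, "complexes.gmt"),
      pathways = file.path(dir, "pathways.gmt"),
      paired = file.path(dir, "paired.tsv"))
    write_data_table(tab, paths$table)
    write.table(ann, paths$annotation, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write_gmt(complexes, paths$complexes)
    write_gmt(pathways, paths$pathways)
    write_data_table(paired, paths$paired)
    out$paths <- paths
  }
  out
}

write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$kind, collection$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Degrade a table for head-to-head comparisons
#'
#' Returns a copy of the table with independent Gaussian noise added to
#' every observed value and, optionally, an extra additive shift applied
#' to the samples of non-reference batches -- emulating a worse
#' processing pipeline for the same study.
#'
#' @param table an [omics_data_table()].
#' @param noise_sd SD of the added noise (same units as the table).
#' @param batch_shift extra shift for non-reference-batch samples;
#'   requires `annotation`.
#' @param annotation annotation `data.frame` (only needed when
#'   `batch_shift != 0`).
#' @param seed RNG seed.
#' @param name name of the degraded table.
#' @return an [omics_data_table()].
#' @export
degrade_table <- function(table, noise_sd, batch_shift = 0,
                          annotation = NULL, seed = 1L, name = "degraded") {
  X <- table$values
  with_seed(seed, {
    X <- X + matrix(rnorm(length(X), sd = noise_sd), nrow(X))
  })
  if (batch_shift != 0) {
    stopifnot(!is.null(annotation),
              identical(annotation$sample, colnames(X)))
    shifted <- annotation$batch != annotation$batch[1L]
    X[, shifted] <- X[, shifted] + batch_shift
  }
  omics_data_table(X, name, scale = table$scale)
}
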