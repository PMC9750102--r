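#' Construct an omics data table
#'
#' The central container every metric consumes: a named feature-by-sample
#' numeric matrix with explicit missing values. `scale` declares whether
#' the values are raw intensities/counts or log2-transformed; it is never
#' sniffed from the data, though an implausible declaration (log2 with a
#' maximum above 50) triggers a non-fatal warning.
#'
#' @param values numeric matrix, features in rows, samples in columns,
#'   with rownames (feature IDs) and colnames (sample IDs).
#' @param name short identifier for the table (e.g. the pipeline that
#'   produced it).
#' @param scale `"raw"` or `"log2"`. On the raw scale all non-missing
#'   values must be non-negative.
#' @return an object of class `omics_data_table`.
#' @export
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(paste0("f", 1:3), c("s1", "s2")))
#' omics_data_table(m, "toy", scale = "raw")
omics_data_table <- function(values, name, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix")
  }
  fid <- rownames(values)
  sid <- colnames(values)
  if (is.null(fid) || any(!nzchar(fid))) {
    stop("table '", name, "': feature IDs (rownames) missing or empty")
  }
  if (is.null(sid) || any(!nzchar(sid))) {
    stop("table '", name, "': sample IDs (colnames) missing or empty")
  }
  if (anyDuplicated(fid)) {
    stop("table '", name, "': duplicated feature IDs: ",
         paste(unique(fid[duplicated(fid)]), collapse = ", "))
  }
  if (anyDuplicated(sid)) {
    stop("table '", name, "': duplicated sample IDs: ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "))
  }
  obs <- values[!is.na(values)]
  if (any(!is.finite(obs))) {
    stop("table '", name, "': non-finite (Inf) values present")
  }
  if (scale == "raw" && any(obs < 0)) {
    stop("table '", name, "': negative values are not allowed on scale 'raw'")
  }
  if (scale == "log2" && length(obs) && max(obs) > 50) {
    warning("table '", name, "' is declared log2 but its maximum is ",
            format(max(obs)), "; check the 'scale' declaration")
  }
  structure(list(name = name, values = values, scale = scale),
            class = "omics_data_table")
}

#' @export
print.omics_data_table <- function(x, ...) {
  nmiss <- sum(is.na(x$values))
  cat(sprintf("omics_data_table '%s': %d features x %d samples (%s scale), %d missing (%.1f%%)\n",
              x$name, nrow(x$values), ncol(x$values), x$scale, nmiss,
              100 * nmiss / max(1, length(x$values))))
  invisible(x)
}

#' @export
dim.omics_data_table <- function(x) dim(x$values)

feature_ids <- function(table) rownames(table$values)
sample_ids  <- function(table) colnames(table$values)

# Features with at least one non-missing value ("identified").
identified_features <- function(table) {
  rownames(table$values)[rowSums(!is.na(table$values)) > 0]
}

# Features non-missing in >= min_fraction of samples ("quantifiable").
quantifiable_features <- function(table, min_fraction = 0.5) {
  frac <- rowMeans(!is.na(table$values))
  rownames(table$values)[frac >= min_fraction]
}

#' Evaluation configuration
#'
#' Bundles every tunable parameter of the evaluation pipeline with its
#' default. All defaults are documented in the package vignette.
#'
#' @param quantifiable_min_fraction fraction of samples in which a feature
#'   must be observed to count as quantifiable (default 0.5).
#' @param cv_threshold QC coefficient-of-variation threshold; the
#'   reproducibility metric is the fraction of features with CV below it
#'   (default 0.30, i.e. "CV less than 30%").
#' @param rwr_restart restart probability of the random walk with restart
#'   (default 0.5).
#' @param rwr_tol L1 convergence tolerance of the walk (default 1e-6).
#' @param network_top_k number of highest-|r| partners each feature is
#'   connected to in the co-expression network (default 10).
#' @param n_pca_components number of principal components used for the
#'   silhouette computation and PCA plots (default 2).
#' @param cv_folds cross-validation folds for class and pathway prediction
#'   (default 5, must be >= 2).
#' @param random_seed seed for every stochastic step (pair sampling, fold
#'   assignment); identical config + seed gives bit-identical results.
#' @param class_column_for_ml annotation column holding the two-level
#'   sample classification used by the supervised metrics.
#' @param log_base_for_cv base used to back-transform log-scale tables
#'   before computing QC CVs (default 2).
#' @param n_complex_pairs number of intra-complex (and inter-complex)
#'   feature pairs sampled for the complex correlation analysis.
#' @return a list of class `evaluation_config`.
#' @export
evaluation_config <- function(quantifiable_min_fraction = 0.5,
                              cv_threshold = 0.30,
                              rwr_restart = 0.5,
                              rwr_tol = 1e-6,
                              network_top_k = 10L,
                              n_pca_components = 2L,
                              cv_folds = 5L,
                              random_seed = 42L,
                              class_column_for_ml = "class",
                              log_base_for_cv = 2,
                              n_complex_pairs = 200L) {
  stopifnot(quantifiable_min_fraction > 0, quantifiable_min_fraction <= 1,
            cv_threshold > 0,
            rwr_restart > 0, rwr_restart < 1,
            rwr_tol > 0,
            network_top_k >= 1,
            n_pca_components > 0,
            cv_folds >= 2,
            n_complex_pairs >= 1)
  structure(list(quantifiable_min_fraction = quantifiable_min_fraction,
                 cv_threshold = cv_threshold,
                 rwr_restart = rwr_restart,
                 rwr_tol = rwr_tol,
                 network_top_k = as.integer(network_top_k),
                 n_pca_components = n_pca_components,
                 cv_folds = as.integer(cv_folds),
                 random_seed = as.integer(random_seed),
                 class_column_for_ml = class_column_for_ml,
                 log_base_for_cv = log_base_for_cv,
                 n_complex_pairs = as.integer(n_complex_pairs)),
            class = "evaluation_config")
}

#' Read an evaluation configuration from YAML
#'
#' Unknown keys are rejected so typos do not silently fall back to
#' defaults.
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [evaluation_config()].
#' @return an `evaluation_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(evaluation_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown configuration key(s) in ", path, ": ",
         paste(bad, collapse = ", "))
  }
  do.call(evaluation_config, vals)
}
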