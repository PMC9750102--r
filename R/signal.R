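#' Intra- versus inter-complex correlation analysis
#'
#' Features of the same protein complex are expected to co-express.
#' Among features present in the table and annotated to at least one
#' complex (the "complex universe"), this samples up to `n_pairs`
#' distinct intra-complex pairs (both members share a complex) and
#' equally many inter-complex pairs (both members annotated but sharing
#' no complex, so the null is matched on annotation coverage), computes
#' the Pearson correlation of each pair on pairwise-complete samples
#' (pairs with fewer than 6 complete samples are dropped), and scores how
#' well the correlation separates intra from inter pairs as an AUROC.
#'
#' @param table an [omics_data_table()].
#' @param complexes a `gene_set_collection` of kind `"complex"`.
#' @param n_pairs number of pairs to sample per group.
#' @param seed RNG seed for pair sampling.
#' @return list of class `complex_correlation_result` with
#'   `intra_correlations`, `inter_correlations` (equal length) and
#'   `separation_auroc`.
#' @export
complex_pair_correlations <- function(table, complexes,
                                      n_pairs = 200L, seed = 42L) {
  stopifnot(inherits(complexes, "gene_set_collection"))
  feats <- feature_ids(table)
  sets <- lapply(complexes$sets, intersect, feats)
  sets <- sets[lengths(sets) >= 2L]
  universe <- sort(unique(unlist(lapply(complexes$sets, intersect, feats))))
  if (!length(sets)) {
    stop("no complex has >= 2 members present in table '", table$name, "'")
  }
  intra <- unique(do.call(rbind, lapply(sets, function(s) {
    t(combn(sort(s), 2L))
  })))
  intra_key <- paste(intra[, 1L], intra[, 2L])
  u <- length(universe)
  n_all <- choose(u, 2)
  inter <- if (n_all <= 2e5) {
    all_pairs <- t(combn(universe, 2L))
    all_pairs[!(paste(all_pairs[, 1L], all_pairs[, 2L]) %in% intra_key), ,
              drop = FALSE]
  } else {
    # large universe: rejection-sample distinct non-sharing pairs
    with_seed(seed + 1L, {
      got <- character(0)
      out <- matrix(character(0), 0, 2)
      while (nrow(out) < 4L * n_pairs && length(got) < 40L * n_pairs) {
        cand <- matrix(universe[sample.int(u, 2L * n_pairs, replace = TRUE)],
                       ncol = 2)
        cand <- cand[cand[, 1L] != cand[, 2L], , drop = FALSE]
        cand <- t(apply(cand, 1L, sort))
        key <- paste(cand[, 1L], cand[, 2L])
        ok <- !(key %in% intra_key) & !(key %in% got) & !duplicated(key)
        got <- c(got, key)
        out <- rbind(out, cand[ok, , drop = FALSE])
      }
      out
    })
  }
  if (nrow(inter) == 0L) stop("no eligible inter-complex pair")
  pair_cor <- function(p) {
    x <- table$values[p[1L], ]
    y <- table$values[p[2L], ]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 6L) return(NA_real_)  # too few complete samples
    suppressWarnings(cor(x[ok], y[ok]))
  }
  n <- min(n_pairs, nrow(intra), nrow(inter))
  if (n < n_pairs) {
    message("complex pairs: only ", n, " eligible pairs per group (asked ",
            n_pairs, ")")
  }
  with_seed(seed, {
    intra_s <- intra[sample.int(nrow(intra), n), , drop = FALSE]
    inter_s <- inter[sample.int(nrow(inter), n), , drop = FALSE]
  })
  r_intra <- apply(intra_s, 1L, pair_cor)
  r_inter <- apply(inter_s, 1L, pair_cor)
  ok <- !is.na(r_intra) & !is.na(r_inter)  # keep groups the same size
  r_intra <- r_intra[ok]
  r_inter <- r_inter[ok]
  if (!length(r_intra)) stop("no pair with >= 6 complete samples")
  structure(list(table_name = table$name,
                 intra_correlations = r_intra,
                 inter_correlations = r_inter,
                 separation_auroc = rank_auroc(pos = r_intra, neg = r_inter)),
            class = "complex_correlation_result")
}

#' Build a co-expression network from a table
#'
#' Restricted to quantifiable features, feature-feature Pearson |r| is
#' computed on pairwise-complete observations (pairs with fewer than 6
#' complete samples are disconnected); each node is connected to its
#' `network_top_k` highest-|r| partners, the edge set symmetrized by
#' union, with edge weight |r|.
#'
#' @param table an [omics_data_table()] with >= 6 samples.
#' @param config an [evaluation_config()].
#' @return list of class `coexpression_network` with `nodes`,
#'   `adjacency` (sparse symmetric `Matrix`, zero diagonal) and
#'   `construction`.
#' @export
build_coexpression_network <- function(table, config = evaluation_config()) {
  if (ncol(table$values) < 6L) stop("network construction needs >= 6 samples")
  keep <- quantifiable_features(table, config$quantifiable_min_fraction)
  if (length(keep) < 2L) stop("< 2 quantifiable features")
  X <- t(table$values[keep, , drop = FALSE])
  R <- abs(suppressWarnings(cor(X, use = "pairwise.complete.obs")))
  ncomp <- crossprod(!is.na(X))
  R[ncomp < 6L] <- NA_real_
  diag(R) <- NA_real_
  p <- length(keep)
  A <- matrix(0, p, p, dimnames = list(keep, keep))
  k <- min(config$network_top_k, p - 1L)
  for (i in seq_len(p)) {
    r <- R[i, ]
    cand <- which(!is.na(r) & r > 0)
    if (!length(cand)) next
    top <- cand[order(r[cand], decreasing = TRUE)][seq_len(min(k, length(cand)))]
    A[i, top] <- r[top]
  }
  A <- pmax(A, t(A))  # union symmetrization, weight |r|
  structure(list(table_name = table$name,
                 nodes = keep,
                 adjacency = Matrix::Matrix(A, sparse = TRUE),
                 construction = list(measure = "pearson_abs",
                                     top_k = config$network_top_k,
                                     weight = "abs_r")),
            class = "coexpression_network")
}

#' Random walk with restart on a co-expression network
#'
#' Iterates `p <- (1 - r) * t(W) %*% p + r * p0`, where `W` is the
#' row-normalized weighted adjacency (so `t(W)` is column-stochastic and
#' each step conserves probability mass) and `p0` is uniform on the seed
#' nodes present in the network, until the L1 change drops below `tol`
#' (or 1000 iterations). Probability mass sitting on zero-degree nodes
#' is redistributed to `p0` each step, so the returned vector always
#' sums to 1.
#'
#' @param network a `coexpression_network`.
#' @param seeds character vector of seed feature IDs.
#' @param restart restart probability in (0, 1).
#' @param tol L1 convergence tolerance.
#' @return named numeric score vector over nodes, summing to 1.
#' @export
rwr_propagate <- function(network, seeds, restart = 0.5, tol = 1e-6) {
  stopifnot(inherits(network, "coexpression_network"),
            restart > 0, restart < 1, tol > 0)
  nodes <- network$nodes
  eff <- intersect(seeds, nodes)
  if (!length(eff)) stop("no seed present in the network")
  A <- network$adjacency
  deg <- Matrix::colSums(A)
  pos <- deg > 0
  # column-stochastic transition: T_ij = A_ij / deg_j. For our symmetric
  # adjacency this is t(W) with W the row-normalized adjacency, so each
  # step conserves probability mass.
  Tm <- A
  if (any(pos)) {
    Tm[, pos] <- Tm[, pos, drop = FALSE] %*%
      Matrix::Diagonal(x = 1 / deg[pos], n = sum(pos))
  }
  p0 <- setNames(numeric(length(nodes)), nodes)
  p0[eff] <- 1 / length(eff)
  p <- p0
  for (it in seq_len(1000L)) {
    dangling <- sum(p[!pos])  # mass on zero-degree nodes -> back to p0
    p_new <- as.numeric((1 - restart) * (Tm %*% p)) +
      (1 - restart) * dangling * p0 + restart * p0
    delta <- sum(abs(p_new - p))
    p <- setNames(p_new, nodes)
    if (delta < tol) break
  }
  p / sum(p)
}

#' Pathway-prediction AUROC via cross-validated network propagation
#'
#' For each pathway with at least `max(5, cv_folds)` members in the
#' network, the members are the positive set and all other network nodes
#' the negative set. Positives are split into `cv_folds` folds (seeded);
#' per fold, the walk is seeded from the training positives and the
#' held-out positives are ranked against all negatives by propagation
#' score; scores are pooled across folds into one AUROC per pathway.
#' Stronger co-expression structure around true pathways gives higher
#' AUROC, i.e. stronger biological signal.
#'
#' @param network a `coexpression_network`.
#' @param pathways a `gene_set_collection` of kind `"pathway"`.
#' @param config an [evaluation_config()].
#' @return list of class `function_prediction_result` with
#'   `per_pathway_auroc` and `median_auroc` (over eligible pathways).
#' @export
function_prediction_auroc <- function(network, pathways,
                                      config = evaluation_config()) {
  stopifnot(inherits(network, "coexpression_network"),
            inherits(pathways, "gene_set_collection"))
  nodes <- network$nodes
  res <- list()
  for (pw in names(pathways$sets)) {
    positives <- intersect(pathways$sets[[pw]], nodes)
    if (length(positives) < max(5L, config$cv_folds)) next  # ineligible
    negatives <- setdiff(nodes, positives)
    if (!length(negatives)) next
    folds <- assign_folds(length(positives), config$cv_folds,
                          seed = config$random_seed)
    pos_scores <- neg_scores <- numeric(0)
    for (f in seq_len(config$cv_folds)) {
      held <- positives[folds == f]
      train <- positives[folds != f]
      if (!length(held) || !length(train)) next
      p <- rwr_propagate(network, train, restart = config$rwr_restart,
                         tol = config$rwr_tol)
      pos_scores <- c(pos_scores, p[held])
      neg_scores <- c(neg_scores, p[negatives])
    }
    res[[pw]] <- rank_auroc(pos = pos_scores, neg = neg_scores)
  }
  if (!length(res)) {
    warning("no pathway with >= max(5, cv_folds) members in the network")
  }
  structure(list(table_name = network$table_name,
                 per_pathway_auroc = unlist(res),
                 median_auroc = if (length(res)) median(unlist(res))
                                else NA_real_),
            class = "function_prediction_result")
}

# Deterministic (near-)balanced fold assignment: shuffle indices under
# the seed, deal them out cyclically.
assign_folds <- function(n, k, seed) {
  with_seed(seed, {
    idx <- sample.int(n)
  })
  folds <- integer(n)
  folds[idx] <- rep_len(seq_len(k), n)
  folds
}

#' Cross-validated class-prediction AUROC
#'
#' For a two-level sample classification (e.g. tumor versus normal), a
#' regularized logistic model (ridge, fixed penalty) is trained on the
#' top 500 most variable quantifiable features -- median-imputed and
#' standardized inside each training fold -- under stratified k-fold
#' cross-validation, and the AUROC computed on pooled out-of-fold
#' scores. QC replicate samples are excluded. Higher AUROC means the
#' table carries stronger class-discriminating biological signal.
#'
#' @param table an [omics_data_table()].
#' @param annotation aligned annotation `data.frame`.
#' @param config an [evaluation_config()].
#' @return list of class `class_prediction_result` with `cv_auroc` and
#'   `out_of_fold_scores` (one per non-QC sample).
#' @export
class_prediction_cv_auroc <- function(table, annotation,
                                      config = evaluation_config()) {
  stopifnot(identical(annotation$sample, sample_ids(table)))
  use <- !annotation$is_qc
  cls <- annotation$class[use]
  lev <- sort(unique(cls))
  if (length(lev) != 2L) {
    stop("class prediction needs exactly 2 class levels, got ",
         length(lev), " (", paste(lev, collapse = ", "), ")")
  }
  if (any(table(cls) < config$cv_folds)) {
    stop("each class needs >= cv_folds (", config$cv_folds, ") samples")
  }
  keep <- quantifiable_features(table, config$quantifiable_min_fraction)
  X <- table$values[keep, use, drop = FALSE]
  v <- apply(X, 1L, var, na.rm = TRUE)
  top <- order(v, decreasing = TRUE)[seq_len(min(500L, nrow(X)))]
  X <- t(X[top, , drop = FALSE])  # samples x features
  if (ncol(X) < 2L) X <- cbind(X, .pad = 0)  # glmnet needs >= 2 columns
  y <- as.integer(cls == lev[2L])
  folds <- integer(length(y))
  for (l in lev) {  # stratified fold assignment, seeded per class
    sel <- which(cls == l)
    folds[sel] <- assign_folds(length(sel), config$cv_folds,
                               seed = config$random_seed + match(l, lev))
  }
  scores <- rep(NA_real_, length(y))
  for (f in seq_len(config$cv_folds)) {
    tr <- folds != f
    Xtr <- X[tr, , drop = FALSE]
    Xte <- X[!tr, , drop = FALSE]
    med <- apply(Xtr, 2L, median, na.rm = TRUE)
    med[is.na(med)] <- 0
    for (j in seq_len(ncol(Xtr))) {
      Xtr[is.na(Xtr[, j]), j] <- med[j]
      Xte[is.na(Xte[, j]), j] <- med[j]
    }
    mu <- colMeans(Xtr)
    sg <- apply(Xtr, 2L, sd)
    sg[sg == 0 | is.na(sg)] <- 1
    Xtr <- scale(Xtr, center = mu, scale = sg)
    Xte <- scale(Xte, center = mu, scale = sg)
    fit <- glmnet::glmnet(Xtr, y[tr], family = "binomial", alpha = 0,
                          lambda = 0.1, standardize = FALSE)
    scores[!tr] <- as.numeric(predict(fit, Xte, type = "response"))
  }
  structure(list(table_name = table$name,
                 cv_auroc = rank_auroc(pos = scores[y == 1L],
                                       neg = scores[y == 0L]),
                 out_of_fold_scores = setNames(scores,
                                               annotation$sample[use])),
            class = "class_prediction_result")
}

#' Clustering concordance with class and batch labels
#'
#' Samples (QC replicates excluded) are clustered hierarchically with
#' distance `1 - Pearson r` (pairwise-complete) and average linkage, the
#' tree cut at k = number of class levels, and the partition compared to
#' the class labels and to the batch labels by adjusted Rand index.
#' High `ari_vs_class` indicates biology-driven grouping (good); high
#' `ari_vs_batch` indicates batch-driven grouping (batch effect).
#'
#' @param table an [omics_data_table()] with >= 4 samples.
#' @param annotation aligned annotation `data.frame`.
#' @return list of class `clustering_result`.
#' @export
clustering_concordance <- function(table, annotation) {
  stopifnot(identical(annotation$sample, sample_ids(table)))
  use <- !annotation$is_qc
  X <- table$values[, use, drop = FALSE]
  cls <- annotation$class[use]
  bat <- annotation$batch[use]
  if (ncol(X) < 4L) stop("clustering needs >= 4 samples")
  k <- length(unique(cls))
  if (k < 2L) stop("clustering concordance needs >= 2 class levels")
  ncomp <- crossprod(!is.na(X))
  if (any(ncomp < 3L)) {
    stop("some sample pair has < 3 complete features; ",
         "filter to deeper features first")
  }
  R <- suppressWarnings(cor(X, use = "pairwise.complete.obs"))
  hc <- hclust(as.dist(1 - R), method = "average")
  cl <- cutree(hc, k = k)
  structure(list(table_name = table$name,
                 linkage_order = colnames(X)[hc$order],
                 cluster_labels = cl,
                 ari_vs_class = mclust::adjustedRandIndex(cl, cls),
                 ari_vs_batch = mclust::adjustedRandIndex(cl, bat)),
            class = "clustering_result")
}
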