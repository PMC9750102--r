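# Independent brute-force oracles used to cross-check the package's
# vectorized/iterative implementations. These deliberately share no code
# with the implementation.

# AUROC by exhaustive pair enumeration, ties counted half.
brute_auroc <- function(pos, neg) {
  wins <- sum(outer(pos, neg, ">"))
  ties <- sum(outer(pos, neg, "=="))
  (wins + 0.5 * ties) / (length(pos) * length(neg))
}

# Silhouette by explicit per-point loops over raw coordinates.
brute_silhouette <- function(coords, labels) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  d <- function(i, j) sqrt(sum((coords[i, ] - coords[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (length(own) == 0L) { s[i] <- 0; next }
    a <- mean(vapply(own, function(j) d(i, j), numeric(1)))
    b <- Inf
    for (l in setdiff(unique(labels), labels[i])) {
      idx <- which(labels == l)
      b <- min(b, mean(vapply(idx, function(j) d(i, j), numeric(1))))
    }
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Stationary RWR distribution by direct linear solve
# p = r (I - (1 - r) W^T)^{-1} p0 with W the row-normalized adjacency
# (t(W) is the column-stochastic transition).
solve_rwr <- function(adjacency, seeds_idx, restart) {
  A <- as.matrix(adjacency)
  n <- nrow(A)
  deg <- rowSums(A)
  W <- sweep(A, 1, ifelse(deg > 0, deg, 1), "/")
  p0 <- numeric(n)
  p0[seeds_idx] <- 1 / length(seeds_idx)
  as.numeric(solve(diag(n) - (1 - restart) * t(W), restart * p0))
}

# Build an omics_data_table from a plain matrix with default dimnames.
make_table <- function(values, name = "t", scale = "log2",
                       feature_ids = NULL, sample_ids = NULL) {
  if (is.null(rownames(values))) {
    rownames(values) <- if (is.null(feature_ids))
      paste0("f", seq_len(nrow(values))) else feature_ids
  }
  if (is.null(colnames(values))) {
    colnames(values) <- if (is.null(sample_ids))
      paste0("s", seq_len(ncol(values))) else sample_ids
  }
  omics_data_table(values, name, scale = scale)
}

# A table whose first columns are QC replicates plus two dummy study
# samples, with matching annotation.
qc_table <- function(values, scale = "raw") {
  n_qc <- ncol(values)
  m <- cbind(values, d1 = values[, 1], d2 = values[, 1])
  colnames(m) <- c(paste0("qc", seq_len(n_qc)), "d1", "d2")
  ann <- make_annotation(colnames(m),
                         class = c(rep("QC", n_qc), "A", "B"),
                         is_qc = c(rep(TRUE, n_qc), FALSE, FALSE))
  list(table = make_table(m, scale = scale), ann = ann)
}

# Minimal annotation for a table's samples.
make_annotation <- function(samples, class = NULL, batch = NULL,
                            is_qc = NULL) {
  n <- length(samples)
  data.frame(sample = samples,
             class = if (is.null(class))
               rep(c("A", "B"), length.out = n) else class,
             batch = if (is.null(batch)) rep("B1", n) else batch,
             order = seq_len(n),
             is_qc = if (is.null(is_qc)) rep(FALSE, n) else is_qc,
             stringsAsFactors = FALSE)
}
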