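make_network <- function(adjacency, nodes = NULL) {
  # assemble a coexpression_network directly for the RWR unit tests
  if (is.null(nodes)) nodes <- rownames(adjacency)
  structure(list(table_name = "toy", nodes = nodes,
                 adjacency = Matrix::Matrix(adjacency, sparse = TRUE),
                 construction = list()),
            class = "coexpression_network")
}

test_that("complex-pair correlations separate latent-factor structure", {
  fx <- generate_fixture(fixture_spec(n_features = 200, n_samples = 50,
                                      n_modules = 4, module_size = 15,
                                      missing_rate = 0, n_qc = 0, seed = 17))
  cc <- complex_pair_correlations(fx$table, fx$complexes, n_pairs = 200,
                                  seed = 17)
  expect_equal(length(cc$intra_correlations),
               length(cc$inter_correlations))
  expect_true(all(abs(c(cc$intra_correlations,
                        cc$inter_correlations)) <= 1))
  expect_gt(cc$separation_auroc, 0.9)
  expect_gt(mean(cc$intra_correlations), mean(cc$inter_correlations))
})

test_that("pure-noise tables show no intra/inter separation", {
  aurocs <- vapply(1:10, function(s) {
    withr::with_seed(s, {
      m <- matrix(rnorm(120 * 30), 120, 30,
                  dimnames = list(sprintf("f%04d", 1:120),
                                  paste0("s", 1:30)))
    })
    sets <- split(rownames(m)[1:60], rep(1:6, each = 10))
    names(sets) <- paste0("c", 1:6)
    cc <- complex_pair_correlations(make_table(m),
                                    gene_set_collection(sets, "complex"),
                                    n_pairs = 150, seed = s)
    cc$separation_auroc
  }, numeric(1))
  expect_lt(abs(mean(aurocs) - 0.5), 0.1)
})

test_that("identical feature rows give an intra-pair correlation of 1", {
  m <- matrix(rnorm(40), 4, 10,
              dimnames = list(paste0("f", 1:4), paste0("s", 1:10)))
  m[2, ] <- m[1, ]
  cc <- complex_pair_correlations(
    make_table(m),
    gene_set_collection(list(c1 = c("f1", "f2"), c2 = c("f3"),
                             c3 = c("f4")), "complex"),
    n_pairs = 5, seed = 1)
  expect_equal(max(cc$intra_correlations), 1, tolerance = 1e-12)
})

test_that("co-expression networks connect correlated features", {
  withr::with_seed(23, {
    m <- rbind(f1 = rnorm(10), f3 = rnorm(10))
  })
  m <- rbind(m[1, , drop = FALSE], f2 = m[1, ], m[2, , drop = FALSE])
  rownames(m) <- c("f1", "f2", "f3")
  colnames(m) <- paste0("s", 1:10)
  net <- build_coexpression_network(make_table(m),
                                    evaluation_config(network_top_k = 1))
  A <- as.matrix(net$adjacency)
  expect_equal(A["f1", "f2"], 1, tolerance = 1e-12)
  expect_identical(A, t(A))
  expect_true(all(diag(A) == 0))
})

test_that("block-structured data yields mostly within-module edges", {
  fx <- generate_fixture(fixture_spec(n_features = 40, n_samples = 50,
                                      n_modules = 2, module_size = 20,
                                      missing_rate = 0, n_qc = 0,
                                      class_effect_sd = 0, seed = 29))
  net <- build_coexpression_network(fx$table,
                                    evaluation_config(network_top_k = 5))
  A <- as.matrix(net$adjacency)
  module <- rep(1:2, each = 20)[match(net$nodes,
                                      rownames(fx$table$values))]
  edges <- which(A > 0 & upper.tri(A), arr.ind = TRUE)
  within <- module[edges[, 1]] == module[edges[, 2]]
  expect_gt(mean(within), 0.95)
})

test_that("random walk with restart matches closed forms and the linear solve", {
  # single node
  n1 <- make_network(matrix(0, 1, 1, dimnames = list("a", "a")))
  expect_equal(unname(rwr_propagate(n1, "a")), 1)

  # two nodes, one edge, restart 0.5: stationary (2/3, 1/3)
  A2 <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  p2 <- rwr_propagate(make_network(A2), "a", restart = 0.5, tol = 1e-12)
  expect_equal(unname(p2), c(2 / 3, 1 / 3), tolerance = 1e-9)

  # linear-solve oracle on random small networks
  withr::with_seed(37, {
    for (rep in 1:10) {
      n <- sample(3:8, 1)
      A <- matrix(0, n, n)
      A[upper.tri(A)] <- runif(n * (n - 1) / 2) *
        (runif(n * (n - 1) / 2) < 0.7)
      A <- A + t(A)
      # ensure no isolated node so the solve oracle applies directly
      for (i in which(rowSums(A) == 0)) A[i, (i %% n) + 1] <-
        A[(i %% n) + 1, i] <- 0.5
      dimnames(A) <- list(paste0("n", 1:n), paste0("n", 1:n))
      seeds <- sample(n, sample(1:2, 1))
      r <- runif(1, 0.2, 0.8)
      p <- rwr_propagate(make_network(A), paste0("n", seeds), restart = r,
                         tol = 1e-10)
      expect_equal(unname(p), solve_rwr(A, seeds, r), tolerance = 1e-6)
      expect_equal(sum(p), 1, tolerance = 1e-9)
    }
  })
})

test_that("RWR handles isolated seed nodes by restart redistribution", {
  A <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  A["b", "c"] <- A["c", "b"] <- 1
  p <- rwr_propagate(make_network(A), "a", restart = 0.5)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_gt(p["a"], p["b"])
  expect_error(rwr_propagate(make_network(A), "zz"), "no seed")
})

test_that("a seed node scores at least what it would as a non-seed", {
  withr::with_seed(43, {
    A <- matrix(runif(36), 6, 6)
    A[lower.tri(A)] <- t(A)[lower.tri(A)]
    diag(A) <- 0
    dimnames(A) <- list(paste0("n", 1:6), paste0("n", 1:6))
  })
  net <- make_network(A)
  with_n1 <- rwr_propagate(net, c("n1", "n2"))
  without_n1 <- rwr_propagate(net, "n2")
  expect_gte(with_n1["n1"], without_n1["n1"])
})

test_that("pathway prediction ranks tight modules highly and applies eligibility", {
  fx <- generate_fixture(fixture_spec(n_features = 120, n_samples = 50,
                                      n_modules = 3, module_size = 15,
                                      missing_rate = 0, n_qc = 0, seed = 53))
  cfg <- evaluation_config(random_seed = 53)
  net <- build_coexpression_network(fx$table, cfg)
  fp <- function_prediction_auroc(net, fx$pathways, cfg)
  expect_equal(length(fp$per_pathway_auroc), 3L)
  expect_gt(fp$median_auroc, 0.9)

  # a 4-member pathway is ineligible with 5 folds
  small <- gene_set_collection(
    list(tiny = feature_ids(fx$table)[1:4],
         big = fx$pathways$sets[[1]]), "pathway")
  fp2 <- function_prediction_auroc(net, small, cfg)
  expect_false("tiny" %in% names(fp2$per_pathway_auroc))

  # no eligible pathway: warning, empty result
  expect_warning(
    fp3 <- function_prediction_auroc(
      net, gene_set_collection(list(tiny = feature_ids(fx$table)[1:4]),
                               "pathway"), cfg),
    "no pathway")
  expect_true(is.na(fp3$median_auroc))
})

test_that("randomly assigned pathways predict at chance level", {
  aurocs <- vapply(1:10, function(s) {
    withr::with_seed(s + 500, {
      m <- matrix(rnorm(100 * 30), 100, 30,
                  dimnames = list(sprintf("f%04d", 1:100),
                                  paste0("s", 1:30)))
      members <- sample(rownames(m), 15)
    })
    cfg <- evaluation_config(random_seed = s)
    net <- build_coexpression_network(make_table(m), cfg)
    fp <- function_prediction_auroc(
      net, gene_set_collection(list(p1 = members), "pathway"), cfg)
    fp$median_auroc
  }, numeric(1))
  expect_lt(abs(mean(aurocs) - 0.5), 0.1)
})

test_that("class prediction separates classes and respects preconditions", {
  fx <- generate_fixture(fixture_spec(n_features = 200, n_samples = 40,
                                      missing_rate = 0.05, n_qc = 0,
                                      class_effect_sd = 1, seed = 59))
  cp <- class_prediction_cv_auroc(fx$table, fx$annotation,
                                  evaluation_config(random_seed = 59))
  expect_gt(cp$cv_auroc, 0.9)
  expect_equal(sort(names(cp$out_of_fold_scores)),
               sort(fx$annotation$sample))
  expect_false(anyNA(cp$out_of_fold_scores))

  # perfectly separable single feature
  m <- matrix(c(rep(0, 10), rep(5, 10)), 1, 20,
              dimnames = list("f1", paste0("s", 1:20)))
  ann <- make_annotation(paste0("s", 1:20),
                         class = rep(c("A", "B"), each = 10))
  cp2 <- class_prediction_cv_auroc(make_table(m), ann)
  expect_equal(cp2$cv_auroc, 1.0)

  ann3 <- make_annotation(paste0("s", 1:20),
                          class = rep(c("A", "B", "C", "D"), 5))
  expect_error(class_prediction_cv_auroc(make_table(m), ann3),
               "exactly 2")
  ann4 <- make_annotation(paste0("s", 1:20),
                          class = rep(c("A", "B"), c(3, 17)))
  expect_error(class_prediction_cv_auroc(make_table(m), ann4),
               "cv_folds")
})

test_that("permuted class labels predict near chance", {
  fx <- generate_fixture(fixture_spec(n_features = 150, n_samples = 40,
                                      missing_rate = 0, n_qc = 0,
                                      class_effect_sd = 1, seed = 61))
  aurocs <- vapply(1:10, function(s) {
    ann <- fx$annotation
    withr::with_seed(s + 900, ann$class <- sample(ann$class))
    class_prediction_cv_auroc(fx$table, ann,
                              evaluation_config(random_seed = s))$cv_auroc
  }, numeric(1))
  expect_lt(abs(mean(aurocs) - 0.5), 0.15)
})

test_that("clustering concordance recovers clean class structure", {
  withr::with_seed(67, {
    m <- matrix(rnorm(50 * 12, sd = 0.3), 50, 12)
    # class-specific signature on half the features (a constant shift of
    # whole samples would be invisible to correlation distance)
    m[1:25, 7:12] <- m[1:25, 7:12] + 5
    m <- m + rnorm(50, sd = 1)  # feature baselines
  })
  dimnames(m) <- list(paste0("f", 1:50), paste0("s", 1:12))
  ann <- make_annotation(paste0("s", 1:12),
                         class = rep(c("A", "B"), each = 6))
  cl <- clustering_concordance(make_table(m), ann)
  expect_equal(cl$ari_vs_class, 1)
  expect_equal(cl$ari_vs_batch, 0)  # single batch partition

  # invariance under sample permutation
  perm <- sample(12)
  ann_p <- ann[perm, ]
  cl_p <- clustering_concordance(make_table(m[, perm]), ann_p)
  expect_equal(cl_p$ari_vs_class, cl$ari_vs_class)

  # random labels on noise cluster near chance
  aris <- vapply(1:10, function(s) {
    withr::with_seed(s + 700, {
      mm <- matrix(rnorm(40 * 20), 40, 20,
                   dimnames = list(paste0("f", 1:40), paste0("s", 1:20)))
      lab <- sample(rep(c("A", "B"), each = 10))
    })
    clustering_concordance(make_table(mm),
                           make_annotation(paste0("s", 1:20),
                                           class = lab))$ari_vs_class
  }, numeric(1))
  expect_lt(abs(mean(aris)), 0.2)
})

test_that("signal metrics are bit-identical across repeated runs", {
  fx <- generate_fixture(fixture_spec(n_features = 100, n_samples = 30,
                                      n_modules = 2, module_size = 15,
                                      seed = 71))
  cfg <- evaluation_config(random_seed = 71)
  run <- function() {
    net <- build_coexpression_network(fx$table, cfg)
    list(cc = complex_pair_correlations(fx$table, fx$complexes,
                                        n_pairs = 50,
                                        seed = cfg$random_seed),
         fp = function_prediction_auroc(net, fx$pathways, cfg),
         cp = class_prediction_cv_auroc(fx$table, fx$annotation, cfg))
  }
  expect_identical(run(), run())
})
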