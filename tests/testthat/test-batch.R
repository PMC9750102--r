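test_that("PCA embedding handles degenerate and clustered inputs", {
  # all samples identical -> no variance anywhere
  m <- matrix(rep(c(1, 5, 3, 8), 4), 4, 4,
              dimnames = list(paste0("f", 1:4), paste0("s", 1:4)))
  emb <- pca_embed(make_table(m), 2)
  expect_true(all(abs(emb$coords) < 1e-10))
  expect_true(all(emb$var_fraction < 1e-10))

  # two sample clusters offset by a constant vector: PC1 separates them
  withr::with_seed(21, {
    base <- matrix(rnorm(200, sd = 0.1), 20, 10)
    base[, 6:10] <- base[, 6:10] + 5
  })
  dimnames(base) <- list(paste0("f", 1:20), paste0("s", 1:10))
  emb2 <- pca_embed(make_table(base + 30), 5)
  expect_gt(emb2$var_fraction[1], max(emb2$var_fraction[-1]))
  expect_true(all(emb2$coords[1:5, 1] < 0) || all(emb2$coords[1:5, 1] > 0))
  expect_true(max(emb2$coords[1:5, 1]) < min(emb2$coords[6:10, 1]) ||
              min(emb2$coords[1:5, 1]) > max(emb2$coords[6:10, 1]))
  # variance fractions agree with the full eigendecomposition
  X <- base + 30
  Xc <- X - rowMeans(X)
  ev <- eigen(crossprod(Xc), symmetric = TRUE)$values
  expect_equal(emb2$var_fraction_all[1:5], (ev / sum(ev))[1:5],
               tolerance = 1e-8)

  # permutation equivariance
  perm <- c(3, 1, 2, 7, 10, 4, 5, 9, 6, 8)
  emb3 <- pca_embed(make_table((base + 30)[, perm]), 5)
  expect_equal(emb3$coords, emb2$coords[perm, ], tolerance = 1e-8)
})

test_that("average silhouette width matches hand computation on 4 points", {
  coords <- matrix(c(0, 1, 10, 11), 4, 1)
  labels <- c("A", "A", "B", "B")
  # point 0: a=1, b=(10+11)/2 ; point 1: a=1, b=(9+10)/2 ; symmetric on B
  expected <- (9.5 / 10.5 + 8.5 / 9.5) / 2
  expect_equal(average_silhouette_width(coords, labels), expected,
               tolerance = 1e-12)
  expect_equal(brute_silhouette(coords, labels), expected,
               tolerance = 1e-12)
})

test_that("silhouette equals the brute-force oracle on random fixtures", {
  withr::with_seed(31, {
    for (rep in 1:20) {
      n <- sample(4:12, 1)
      coords <- matrix(rnorm(n * 2), n, 2)
      labels <- sample(c("A", "B", "C"), n, replace = TRUE)
      if (length(unique(labels)) < 2) next
      expect_equal(average_silhouette_width(coords, labels),
                   brute_silhouette(coords, labels), tolerance = 1e-12)
    }
  })
  expect_error(average_silhouette_width(matrix(1:4, 4, 1), rep("A", 4)),
               "single label")
})

test_that("random labels on a Gaussian cloud give near-zero silhouette", {
  withr::with_seed(41, {
    vals <- replicate(100, {
      coords <- matrix(rnorm(60), 30, 2)
      average_silhouette_width(coords, sample(c("A", "B"), 30, TRUE))
    })
  })
  expect_lt(abs(mean(vals)), 0.05)
})

test_that("principal component regression reproduces hand ANOVA results", {
  # all variance in PC1, batch perfectly determines the scores
  coords <- cbind(PC1 = c(-1, -1, -1, 1, 1, 1), PC2 = rep(0, 6))
  labels <- c("A", "A", "A", "B", "B", "B")
  expect_equal(principal_component_regression(coords, c(1, 0), labels), 1)

  # hand ANOVA on unbalanced scores: R2 = SSB / SST
  y <- c(1, 2, 3, 6, 7)
  g <- c("A", "A", "A", "B", "B")
  ssb <- 3 * (2 - mean(y))^2 + 2 * (6.5 - mean(y))^2
  sst <- sum((y - mean(y))^2)
  expect_equal(principal_component_regression(cbind(y), 1, g),
               ssb / sst, tolerance = 1e-12)

  # invariance to label renaming and sample permutation
  withr::with_seed(13, {
    coords2 <- matrix(rnorm(40), 20, 2)
    lab <- sample(c("x", "y"), 20, TRUE)
  })
  vf <- c(0.6, 0.4)
  r <- principal_component_regression(coords2, vf, lab)
  relab <- c(x = "batch9", y = "batch1")[lab]
  expect_equal(principal_component_regression(coords2, vf, relab), r)
  perm <- sample(20)
  expect_equal(principal_component_regression(coords2[perm, ], vf,
                                              lab[perm]), r)
})

test_that("random grouping yields the expected small PCR R2", {
  # E[R2] of regressing iid scores on a random g-level factor is
  # (g - 1) / (n - 1)
  n <- 60
  withr::with_seed(51, {
    r2 <- replicate(200, {
      principal_component_regression(cbind(rnorm(n)), 1,
                                     sample(c("A", "B"), n, TRUE))
    })
  })
  expect_lt(abs(mean(r2) - 1 / (n - 1)), 0.005)
})

test_that("sample correlations use pairwise-complete data and flag thin pairs", {
  withr::with_seed(61, {
    m <- matrix(rnorm(60), 20, 3,
                dimnames = list(paste0("f", 1:20), paste0("s", 1:3)))
  })
  m2 <- cbind(m, s4 = m[, 1])                     # duplicated sample
  m2 <- cbind(m2, s5 = -(m[, 1] - mean(m[, 1])))  # negated centered copy
  R <- sample_correlation_matrix(make_table(m2))
  expect_equal(R["s1", "s4"], 1, tolerance = 1e-12)
  expect_equal(R["s1", "s5"], -1, tolerance = 1e-12)
  # brute-force per-pair oracle
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(R[i, j], cor(m2[, i], m2[, j]), tolerance = 1e-12)
  }

  m3 <- m
  m3[3:20, 3] <- NA  # only 2 complete features against the others
  expect_warning(R3 <- sample_correlation_matrix(make_table(m3)),
                 "< 3 complete")
  expect_true(is.na(R3["s1", "s3"]))
})

test_that("batch assessment skips the metrics for a single batch", {
  fx <- generate_fixture(fixture_spec(n_features = 60, n_samples = 10,
                                      n_modules = 2, module_size = 10,
                                      n_batches = 1, n_qc = 0, seed = 9))
  expect_warning(b <- batch_assessment(fx$table, fx$annotation),
                 "single batch")
  expect_true(is.na(b$asw_batch))
  expect_true(is.na(b$pcr_batch_r2))
  expect_false(anyNA(b$pca_coords))
})
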