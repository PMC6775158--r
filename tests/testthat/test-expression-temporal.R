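test_that("TPM matches hand arithmetic and sums to 1e6 per sample", {
  counts <- matrix(c(10, 10), ncol = 1, dimnames = list(c("t1", "t2"), "s1"))
  tpm <- compute_tpm(counts, c(t1 = 1000, t2 = 2000))
  expect_equal(tpm[, 1], c(t1 = 2e6 / 3, t2 = 1e6 / 3), tolerance = 1e-9)

  single <- matrix(5, dimnames = list("t1", "s1"))
  expect_equal(compute_tpm(single, c(t1 = 500))[1, 1], 1e6)

  eqc <- matrix(7, nrow = 4, ncol = 2,
                dimnames = list(paste0("t", 1:4), c("s1", "s2")))
  tpm <- compute_tpm(eqc, setNames(rep(100, 4), paste0("t", 1:4)))
  expect_true(all(abs(tpm - 1e6 / 4) < 1e-9))

  zero <- matrix(c(1, 0, 2, 0), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  zero[, 2] <- 0
  expect_error(compute_tpm(zero, c(a = 10, b = 10)), "all-zero")
})

test_that("TPM column normalization is not preserved under row subsetting", {
  set.seed(1)
  counts <- matrix(rpois(40, 50), 8, 5,
                   dimnames = list(paste0("t", 1:8), paste0("s", 1:5)))
  len <- setNames(runif(8, 500, 2000), paste0("t", 1:8))
  tpm <- compute_tpm(counts, len)
  sub <- tpm[1:4, ]
  expect_false(all(abs(colSums(sub) - 1e6) < 1))
  # recomputation restores the invariant
  re <- compute_tpm(counts[1:4, ], len)
  expect_true(all(abs(colSums(re) - 1e6) < 1e-6))
})

test_that("Z-scores standardize each retained row and flag constant rows", {
  # choose TPMs so that log2(tpm + 1) = 1, 2, 3
  m <- rbind(a = c(1, 3, 7), b = c(5, 5, 5))
  colnames(m) <- paste0("s", 1:3)
  z <- log_zscore(m)
  expect_equal(unname(z$z["a", ]), c(-1, 0, 1))
  expect_equal(z$flagged, "b")
  expect_false("b" %in% rownames(z$z))
  expect_equal(sum(z$z["a", ]), 0)
  expect_equal(sd(z$z["a", ]), 1)
})

test_that("BH adjustment matches the step-up definition on random vectors", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.42), 0.42)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")

  set.seed(11)
  for (i in 1:1000) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), brute_bh(p), tolerance = 1e-12)
  }
})

test_that("NB testing returns null results for identical counts", {
  samples <- toy_samples()
  counts <- matrix(50, nrow = 3, ncol = nrow(samples),
                   dimnames = list(paste0("f", 1:3), samples$sample_id))
  res <- nb_differential(counts, samples)
  expect_true(all(abs(res$log2fc_2) < 1e-12))
  expect_true(all(res$p_2 > 0.999))
  expect_true(all(res$lrt_p > 0.999))
})

test_that("NB testing requires two replicates per group and filters low counts", {
  samples <- toy_samples(reps = 1)
  counts <- matrix(10, 2, nrow(samples),
                   dimnames = list(c("a", "b"), samples$sample_id))
  expect_error(nb_differential(counts, samples), "2 replicates")

  samples <- toy_samples()
  counts <- matrix(rpois(2 * nrow(samples), 40), 2, nrow(samples),
                   dimnames = list(c("a", "b"), samples$sample_id))
  counts["b", ] <- 0
  counts["b", 1] <- 5  # total below the filter
  res <- nb_differential(counts, samples)
  expect_true(res$filtered[res$feature_id == "b"])
  expect_true(is.na(res$lrt_p[res$feature_id == "b"]))
})

test_that("LRT p-values are approximately uniform under the NB null", {
  samples <- toy_samples()
  set.seed(1)
  ks <- vapply(1:3, function(r) {
    mu <- rlnorm(500, log(100), 0.7)
    counts <- matrix(rnbinom(500 * nrow(samples), size = 10,
                             mu = rep(mu, nrow(samples))),
                     nrow = 500,
                     dimnames = list(sprintf("f%03d", 1:500),
                                     samples$sample_id))
    res <- nb_differential(counts, samples)
    suppressWarnings(ks.test(res$lrt_p, "punif")$p.value)
  }, 0)
  expect_gt(median(ks), 0.01)
})

test_that("a planted 4-fold change at 2 dpi is detected by the Wald test", {
  samples <- toy_samples()
  set.seed(2)
  mu <- rlnorm(500, log(100), 0.7)
  MU <- matrix(rep(mu, nrow(samples)), 500)
  planted <- 1:100
  MU[planted, samples$timepoint_dpi == 2] <-
    MU[planted, samples$timepoint_dpi == 2] * 4
  counts <- matrix(rnbinom(length(MU), size = 10, mu = MU), nrow = 500,
                   dimnames = list(sprintf("f%03d", 1:500),
                                   samples$sample_id))
  res <- nb_differential(counts, samples)
  expect_gte(mean(res$p_2[planted] < 0.05), 0.8)
  expect_true(all(res$log2fc_2[planted][res$p_2[planted] < 1e-4] > 0))
})

test_that("K-means recovers a separable two-archetype partition exactly", {
  set.seed(3)
  a <- matrix(rnorm(50 * 6, 0, 0.1), 50, 6) +
    matrix(rep(c(2, 2, 2, -2, -2, -2), each = 50), 50, 6)
  b <- -a + matrix(rnorm(50 * 6, 0, 0.1), 50, 6)
  z <- rbind(a, b)
  rownames(z) <- sprintf("t%03d", 1:100)
  cl <- kmeans_temporal(z, K = 2, seed = 1, n_restarts = 5)
  truth <- rep(1:2, each = 50)
  expect_equal(adjusted_rand_index(cl$assignment, truth), 1)
  # independent cross-check against stats::kmeans on the same data
  ref <- stats::kmeans(z, centers = 2, nstart = 10)
  expect_equal(adjusted_rand_index(cl$assignment, ref$cluster), 1)
  expect_equal(cl$within_ss, ref$tot.withinss, tolerance = 1e-6)
})

test_that("K-means is deterministic given its seed and validates K", {
  set.seed(4)
  z <- matrix(rnorm(200), 40, 5, dimnames = list(sprintf("t%02d", 1:40), NULL))
  c1 <- kmeans_temporal(z, K = 4, seed = 9)
  c2 <- kmeans_temporal(z, K = 4, seed = 9)
  expect_identical(c1$assignment, c2$assignment)
  expect_identical(c1$within_ss, c2$within_ss)
  expect_error(kmeans_temporal(z, K = 1, seed = 1), "at least 2")
  expect_error(kmeans_temporal(z, K = 41, seed = 1), "exceeds")
  # reported within-SS equals the sum of squared distances to centroids
  d2 <- sum((z - c1$centroids[c1$assignment, ])^2)
  expect_equal(c1$within_ss, d2, tolerance = 1e-9)
  # every cluster nonempty
  expect_true(all(tabulate(c1$assignment, 4) > 0))
})

test_that("adjusted Rand index agrees with mclust on random labelings", {
  set.seed(5)
  for (i in 1:20) {
    a <- sample(1:4, 60, replace = TRUE)
    b <- sample(1:5, 60, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:10, 1:10), 1)
})
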