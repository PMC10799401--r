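test_that("count simulation is deterministic given the seed", {
  a <- simulate_counts(n_samples = 40, n_groups = 4,
                       genes_per_omic = c(50, 80), seed = 123)
  b <- simulate_counts(n_samples = 40, n_groups = 4,
                       genes_per_omic = c(50, 80), seed = 123)
  expect_identical(a, b)
  c2 <- simulate_counts(n_samples = 40, n_groups = 4,
                        genes_per_omic = c(50, 80), seed = 124)
  expect_false(identical(a$omics, c2$omics))
})

test_that("simulated counts satisfy the declared contract", {
  sim <- simulate_counts(n_samples = 60, n_groups = 5,
                         genes_per_omic = c(100, 200), seed = 2)
  expect_length(sim$omics, 2)
  expect_identical(dim(sim$omics[[1]]), c(60L, 100L))
  expect_identical(dim(sim$omics[[2]]), c(60L, 200L))
  for (m in sim$omics) {
    expect_true(all(m >= 0))
    expect_true(all(m == round(m)))
    expect_identical(rownames(m), names(sim$truth))
  }
  expect_length(sim$truth, 60)
  expect_true(all(tabulate(sim$truth, 5) >= 2))
})

test_that("counts are over-dispersed relative to Poisson for positive dispersion", {
  sim <- simulate_counts(n_samples = 200, n_groups = 1,
                         genes_per_omic = 300, de_prob = 0.5,
                         dispersion = 0.3, seed = 5)
  m <- sim$omics[[1]]
  mu <- colMeans(m); v <- apply(m, 2, var)
  hi <- mu > stats::quantile(mu, 0.5)     # high-expression genes
  expect_gt(mean(v[hi] > mu[hi]), 0.95)
})

test_that("group signal controls recoverability end to end", {
  # no group effect: labels cannot be recovered
  nmis <- vapply(1:3, function(s) {
    sim <- simulate_counts(n_samples = 80, n_groups = 4,
                           genes_per_omic = c(100, 150),
                           de_prob = 0.1, de_fold = 0, seed = s)
    fit <- mosd(lapply(sim$omics, normalize_counts),
                n_clusters = 4, seed = s)
    nmi(fit$labels, sim$truth)
  }, numeric(1))
  expect_lt(mean(nmis), 0.2)

  # strong effect: near-perfect recovery
  sim <- simulate_counts(n_samples = 80, n_groups = 4,
                         genes_per_omic = c(100, 150),
                         de_prob = 0.5, de_fold = 1.5, seed = 9)
  fit <- mosd(lapply(sim$omics, normalize_counts), n_clusters = 4, seed = 9)
  expect_gte(nmi(fit$labels, sim$truth), 0.8)
})

test_that("blob generator spans the unrecoverable-to-separable range", {
  flat <- simulate_blobs(60, 3, dims = c(6, 6), separation = 0, seed = 1)
  fit0 <- mosd(flat, n_clusters = 3, seed = 1)
  expect_lt(nmi(fit0$labels, flat$truth), 0.2)

  sep <- simulate_blobs(60, 3, dims = c(6, 6), separation = 20, seed = 1)
  fit1 <- mosd(sep, n_clusters = 3, seed = 1)
  expect_equal(ari(fit1$labels, sep$truth), 1)

  expect_error(simulate_blobs(20, 5, dims = 3, separation = 2, seed = 1),
               "at least n_groups features")
})

test_that("the larger-feature omic dominates a conflicting fusion", {
  # two omics with contradictory group structure; the softmax weight of the
  # wide omic exceeds the narrow one's, so fused labels follow the wide omic
  withr::with_seed(31, {
    truth_a <- rep(1:2, each = 20)
    truth_b <- rep(1:2, times = 20)
    narrow <- matrix(rnorm(40 * 10), 40, 10)
    narrow[truth_a == 2, 1:5] <- narrow[truth_a == 2, 1:5] + 4
    wide <- matrix(rnorm(40 * 400), 40, 400)
    wide[truth_b == 2, 1:200] <- wide[truth_b == 2, 1:200] + 4
    rownames(narrow) <- rownames(wide) <- sprintf("S%02d", 1:40)
  })
  fit <- mosd(list(narrow = narrow, wide = wide), n_clusters = 2, seed = 1)
  expect_gt(fit$weights[2], fit$weights[1])
  expect_gt(nmi(fit$labels, truth_b), nmi(fit$labels, truth_a))
})
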