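# naive transition-matrix oracle: explicit sort per row
brute_transition <- function(S, knn) {
  n <- nrow(S)
  TT <- matrix(0, n, n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    nb <- others[order(S[i, others], decreasing = TRUE)][seq_len(knn)]
    TT[i, nb] <- S[i, nb] / sum(S[i, nb])
  }
  TT
}

test_that("transition matrix is the kNN-masked row normalization", {
  # equal off-diagonal entries, full neighborhood: uniform rows
  S <- matrix(0.4, 5, 5); diag(S) <- 1
  TT <- transition_matrix(S, 4)
  expect_true(all(abs(TT[row(TT) != col(TT)] - 0.25) < 1e-12))
  expect_true(all(diag(TT) == 0))

  # worked 3-sample instance: row (., 0.6, 0.2), knn = 2 -> (0, 0.75, 0.25)
  S3 <- rbind(c(1, 0.6, 0.2), c(0.6, 1, 0.5), c(0.2, 0.5, 1))
  expect_equal(transition_matrix(S3, 2)[1, ], c(0, 0.75, 0.25))

  expect_error(transition_matrix(S3, 3), "knn must satisfy")
})

test_that("transition rows are stochastic and zero outside neighborhoods", {
  for (seed in 1:4) {
    S <- random_affinity(12, seed = seed)
    knn <- c(2, 4, 6, 11)[seed]
    TT <- transition_matrix(S, knn)
    expect_equal(unname(rowSums(TT)), rep(1, 12), tolerance = 1e-10)
    expect_true(all(TT >= 0))
    expect_identical(unname(rowSums(TT > 0)), rep(knn, 12L))
    expect_equal(TT, brute_transition(S, knn), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("one diffusion step with alpha = 1 and full neighborhood is S %*% T", {
  S <- random_affinity(8, seed = 5)
  TT <- transition_matrix(S, 7)
  M <- self_diffuse(S, knn = 7, alpha = 1, t = 1)
  dense <- S %*% TT
  expect_equal(unname(M), unname((dense + t(dense)) / 2), tolerance = 1e-12)
})

test_that("diffusion matches the step-by-step dense oracle", {
  S <- random_affinity(6, seed = 9)
  TT <- brute_transition(S, 3)
  M <- S
  for (step in 1:3) M <- 0.8 * (M %*% TT) + 0.2 * diag(6)
  M <- (M + t(M)) / 2
  expect_equal(unname(self_diffuse(S, knn = 3, alpha = 0.8, t = 3)),
               unname(M), tolerance = 1e-10)
})

test_that("diffusion preserves disconnected blocks and t = 0 is the identity op", {
  S <- block_affinity(c(4, 5), within = 0.7)
  M <- self_diffuse(S, knn = 2, alpha = 0.8, t = 4)
  expect_true(all(M[1:4, 5:9] == 0))      # no cross-block mass, exactly
  expect_true(all(M >= 0))
  expect_identical(self_diffuse(S, knn = 2, alpha = 0.8, t = 0), S)
})

test_that("diffusion widens the within-between similarity gap on noisy blobs", {
  sim <- simulate_blobs(60, 3, dims = c(8, 8), separation = 3.5, seed = 11)
  affs <- lapply(sim$omics, local_scaling_affinity, k = 5)
  S <- fuse_affinities(affs, feature_weights(c(8, 8)))
  gap <- function(M) {
    same <- outer(sim$truth, sim$truth, "==") & row(M) != col(M)
    mean(M[same]) - mean(M[!same & row(M) != col(M)])
  }
  Sd <- self_diffuse(S, knn = 5, alpha = 0.8, t = 3)
  # rescale: diffusion shrinks absolute values, compare relative contrast
  expect_gt(gap(Sd) / mean(Sd[row(Sd) != col(Sd)]),
            gap(S) / mean(S[row(S) != col(S)]))
})
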