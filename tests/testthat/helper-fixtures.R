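# Fixtures built in code: exact block-diagonal networks and small random
# affinities used across the suite.

# exact block-diagonal similarity: `within` inside blocks, 0 between, 1 diag
block_affinity <- function(sizes, within = 0.8) {
  n <- sum(sizes)
  S <- matrix(0, n, n)
  stop_at <- cumsum(sizes)
  start_at <- c(1L, head(stop_at, -1L) + 1L)
  for (b in seq_along(sizes)) {
    idx <- start_at[b]:stop_at[b]
    S[idx, idx] <- within
  }
  diag(S) <- 1
  rownames(S) <- colnames(S) <- sprintf("S%03d", seq_len(n))
  S
}

block_truth <- function(sizes) rep(seq_along(sizes), sizes)

# a valid affinity matrix from random Gaussian data
random_affinity <- function(n, d = 4, k = 3, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * d), n, d)
    rownames(X) <- sprintf("S%03d", seq_len(n))
    local_scaling_affinity(X, k = k)
  })
}

# naive O(n^2 d) Euclidean distance oracle
brute_distances <- function(X) {
  n <- nrow(X)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    D[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
  D
}
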