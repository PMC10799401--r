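#' Euclidean distance matrix between samples
#'
#' @param X Numeric matrix, samples in rows.
#' @return Symmetric n x n matrix of Euclidean distances with zero diagonal,
#'   sample IDs on both axes.
#' @export
pairwise_distances <- function(X) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("X contains non-finite values")
  G <- tcrossprod(X)
  sq <- diag(G)
  D2 <- outer(sq, sq, "+") - 2 * G
  D2[D2 < 0] <- 0           # numerical negatives from cancellation
  D <- sqrt(D2)
  D <- (D + t(D)) / 2
  diag(D) <- 0
  rownames(D) <- colnames(D) <- rownames(X)
  D
}

#' Local scale of each sample: distance to its k-th nearest neighbor
#'
#' The local scale sigma_i is the distance from sample i to its k-th nearest
#' neighbor (self excluded, distance ties broken by sample index). It is the
#' per-sample bandwidth of the self-tuning affinity: dense neighborhoods get
#' small scales, sparse ones large, so the affinity adapts across density
#' regimes.
#'
#' Duplicate samples give sigma_i = 0, which would put a zero in the affinity
#' denominator; such scales are replaced by the smallest positive distance
#' from i (with a warning), or by a tiny positive floor if every distance
#' from i is zero.
#'
#' @param D Symmetric distance matrix ([pairwise_distances()]).
#' @param k Neighbor rank used for the scale, `1 <= k <= n - 1`.
#' @return Numeric vector of n positive local scales.
#' @export
local_scales <- function(D, k) {
  n <- nrow(D)
  k <- as.integer(k)
  if (k < 1L || k >= n) stop("k must satisfy 1 <= k <= n - 1 (n = ", n, ")")
  sig <- numeric(n)
  for (i in seq_len(n)) {
    d <- D[i, -i]
    ord <- order(d)            # stable: ties broken by sample index
    sig[i] <- d[ord[k]]
    if (sig[i] == 0) {
      pos <- d[d > 0]
      if (length(pos) > 0L) {
        sig[i] <- min(pos)
        warning("sample ", i, " has duplicate neighbors; local scale ",
                "replaced by smallest positive distance")
      } else {
        sig[i] <- .Machine$double.eps
        warning("sample ", i, " is identical to all others; local scale ",
                "set to a tiny floor")
      }
    }
  }
  sig
}

#' Local-scaling (self-tuning) affinity matrix for one omic
#'
#' Builds the n x n affinity `A(i,j) = exp(-d^2(x_i, x_j) / (sigma_i *
#' sigma_j))` where `d` is Euclidean distance and `sigma_i` is the distance
#' from sample i to its k-th nearest neighbor ([local_scales()]). Dividing
#' the squared distance by the product of the two local scales makes the
#' similarity self-tuning: it is invariant to a global rescaling of the
#' features and balances dense and sparse regions of the cohort.
#'
#' @param X Numeric matrix, samples in rows (one omic).
#' @param k Neighborhood size for the local scales (default 5).
#' @return Symmetric n x n affinity matrix with entries in `[0, 1]` and unit
#'   diagonal; attribute `"k"` records the neighborhood size.
#' @examples
#' X <- matrix(c(0, 1, 3, 6), ncol = 1)
#' A <- local_scaling_affinity(X, k = 1)
#' A[1, 2]  # exp(-1)
#' @export
local_scaling_affinity <- function(X, k = 5L) {
  affinity_from_distances(pairwise_distances(X), k)
}

#' Local-scaling affinity from a precomputed distance matrix
#'
#' Same kernel as [local_scaling_affinity()], starting from an existing
#' Euclidean distance matrix — useful when sweeping the neighborhood size
#' `k`, where the distances can be computed once.
#'
#' @param D Symmetric distance matrix with zero diagonal
#'   ([pairwise_distances()]).
#' @param k Neighborhood size for the local scales.
#' @return Symmetric affinity matrix with entries in `[0, 1]`, unit
#'   diagonal.
#' @export
affinity_from_distances <- function(D, k = 5L) {
  sig <- local_scales(D, k)
  A <- exp(-(D^2) / outer(sig, sig))
  A <- (A + t(A)) / 2
  diag(A) <- 1               # d(i,i) = 0 forces exp(0); fixed exactly
  rownames(A) <- colnames(A) <- rownames(D)
  attr(A, "k") <- as.integer(k)
  A
}
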