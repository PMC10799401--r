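#' kNN-masked row-stochastic transition matrix
#'
#' For each sample i, the `knn` most similar other samples (ties broken by
#' sample index) keep their similarity, everything else is zeroed, and the
#' row is normalized to sum to one:
#' `T(i,j) = S(i,j) / sum_{l in knn(i)} S(i,l)` if `j` is in `knn(i)`, else 0.
#' Restricting to nearest neighbors encodes the assumption that local
#' similarities are more reliable than remote ones.
#'
#' @param S Symmetric non-negative similarity matrix.
#' @param knn Neighborhood size, `1 <= knn <= n - 1`.
#' @return n x n row-stochastic matrix, zero outside each row's
#'   neighborhood (diagonal excluded from neighborhoods).
#' @export
transition_matrix <- function(S, knn) {
  n <- nrow(S)
  knn <- as.integer(knn)
  if (knn < 1L || knn >= n) stop("knn must satisfy 1 <= knn <= n - 1")
  TT <- matrix(0, n, n, dimnames = dimnames(S))
  for (i in seq_len(n)) {
    s <- S[i, ]
    s[i] <- -Inf                       # self excluded from the neighborhood
    nb <- order(s, decreasing = TRUE)[seq_len(knn)]
    tot <- sum(S[i, nb])
    if (tot <= 0) stop("row ", i, " has no positive similarity among its neighbors")
    TT[i, nb] <- S[i, nb] / tot
  }
  TT
}

#' Self-diffusion of a fused similarity network
#'
#' Iterates `S_{t+1} = alpha * S_t %*% T + (1 - alpha) * I` for `t`
#' steps, where `T` is the kNN-masked row-stochastic transition matrix of the
#' *initial* network ([transition_matrix()], held fixed across iterations)
#' and the identity term re-injects self-similarity so the iteration cannot
#' collapse. Diffusion accumulates reliable local similarities into
#' longer-range ones, tightening within-cluster similarity and sharpening
#' cluster boundaries; too many iterations oversmooth.
#'
#' Right-multiplication loses exact symmetry, so the final iterate is
#' symmetrized as `(M + t(M)) / 2` (the spectral step expects a symmetric
#' matrix). Intermediate iterates are not symmetrized.
#'
#' @param S Fused similarity network ([fuse_affinities()]).
#' @param knn Neighborhood size for the transition matrix (default 5,
#'   matching the affinity neighborhood).
#' @param alpha Retention weight in (0, 1]; default 0.8 keeps diffusion
#'   dominant while anchoring the identity.
#' @param t Number of diffusion steps (default 3). `t = 0` returns `S`
#'   unchanged, allowing diffusion-free ablations.
#' @return Diffused symmetric non-negative similarity matrix.
#' @export
self_diffuse <- function(S, knn = 5L, alpha = 0.8, t = 3L) {
  stopifnot(alpha > 0, alpha <= 1)
  t <- as.integer(t)
  if (t < 0L) stop("t must be >= 0")
  if (t == 0L) return(S)
  TT <- transition_matrix(S, knn)
  M <- S
  I <- diag(nrow(S))
  for (step in seq_len(t)) {
    M <- alpha * (M %*% TT) + (1 - alpha) * I
  }
  M <- (M + t(M)) / 2
  dimnames(M) <- dimnames(S)
  M
}
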