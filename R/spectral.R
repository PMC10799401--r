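#' Symmetric normalized graph Laplacian
#'
#' `L = I - D^{-1/2} S D^{-1/2}` with `D` the diagonal degree matrix of `S`.
#' `L` is symmetric positive semi-definite with eigenvalues in `[0, 2]`; its
#' smallest eigenvectors embed the graph for clustering.
#'
#' @param S Symmetric non-negative similarity matrix with no zero-degree row.
#' @return Symmetric n x n Laplacian matrix.
#' @export
normalized_laplacian <- function(S) {
  if (max(abs(S - t(S))) > 1e-8) stop("S must be symmetric")
  deg <- rowSums(S)
  if (any(deg <= 0)) {
    bad <- which(deg <= 0)[1L]
    nm <- if (!is.null(rownames(S))) rownames(S)[bad] else bad
    stop("sample '", nm, "' is isolated (zero degree)")
  }
  dinv <- 1 / sqrt(deg)
  L <- -S * outer(dinv, dinv)
  diag(L) <- diag(L) + 1
  (L + t(L)) / 2
}

#' Spectral embedding: eigenvectors of the C smallest Laplacian eigenvalues
#'
#' @param S Similarity matrix.
#' @param C Embedding dimension (number of clusters sought).
#' @return List with `vectors` (n x C matrix `H`, columns orthonormal) and
#'   `values` (the C smallest eigenvalues of the normalized Laplacian,
#'   ascending).
#' @export
spectral_embedding <- function(S, C) {
  n <- nrow(S)
  C <- as.integer(C)
  if (C < 1L || C > n) stop("C must be between 1 and n")
  L <- normalized_laplacian(S)
  e <- eigen(L, symmetric = TRUE)      # eigenvalues in decreasing order
  idx <- rev(seq(n - C + 1L, n))       # smallest C, ascending
  list(vectors = e$vectors[, idx, drop = FALSE], values = e$values[idx])
}

#' Spectral clustering of a similarity network
#'
#' Embeds the samples with the eigenvectors of the `C` smallest eigenvalues
#' of the normalized Laplacian and partitions the embedded rows with k-means
#' (50 restarts, fixed seed, so the result is reproducible). By default the
#' embedding rows are used as-is; `norm_rows = TRUE` applies the common
#' variant that L2-normalizes each row before k-means.
#'
#' @param S Symmetric non-negative similarity matrix.
#' @param C Number of clusters, `2 <= C <= n - 1`.
#' @param seed Integer seed for the k-means restarts.
#' @param norm_rows L2-normalize embedding rows before k-means? Default
#'   `FALSE`.
#' @param nstart Number of k-means restarts (default 50).
#' @return Integer vector of cluster labels in `1..C`, named by sample ID;
#'   every cluster is non-empty.
#' @export
spectral_cluster <- function(S, C, seed = 1L, norm_rows = FALSE, nstart = 50L) {
  n <- nrow(S)
  C <- as.integer(C)
  if (C < 2L || C > n - 1L) stop("C must satisfy 2 <= C <= n - 1")
  H <- spectral_embedding(S, C)$vectors
  if (norm_rows) {
    nr <- sqrt(rowSums(H^2))
    nr[nr == 0] <- 1
    H <- H / nr
  }
  km <- NULL
  for (attempt in 0:2) {               # rare empty-cluster failures: reseed
    km <- tryCatch(
      withr::with_seed(as.integer(seed) + attempt,
                       stats::kmeans(H, centers = C, nstart = nstart,
                                     iter.max = 100L)),
      error = function(e) e)
    if (!inherits(km, "error")) break
  }
  if (inherits(km, "error"))
    stop("k-means failed after retries: ", conditionMessage(km))
  labels <- as.integer(km$cluster)
  names(labels) <- rownames(S)
  labels
}
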