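#' Normalized mutual information between two partitions
#'
#' `NMI(a, b) = I(a; b) / ((H(a) + H(b)) / 2)` — mutual information
#' normalized by the arithmetic mean of the two label entropies (natural
#' logs; the normalization variant is fixed and documented here because
#' several exist). NMI is symmetric, invariant to relabeling on either side,
#' 1 iff the partitions are identical up to renaming, and 0 for independent
#' partitions. If both sides are the trivial single-cluster partition the
#' partitions are identical and NMI is defined as 1 (with a warning).
#'
#' @param a,b Cluster label vectors over the same samples (any atomic type).
#' @return NMI in `[0, 1]`.
#' @examples
#' nmi(c(1, 1, 2, 2), c(2, 2, 1, 1))  # 1: same partition, renamed
#' nmi(c(1, 1, 2, 2), c(1, 2, 1, 2))  # 0: independent
#' @export
nmi <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  n <- length(a)
  joint <- table(a, b) / n
  pa <- rowSums(joint); pb <- colSums(joint)
  if (length(pa) == 1L && length(pb) == 1L) {
    warning("both partitions are a single cluster; NMI defined as 1")
    return(1)
  }
  nz <- joint > 0
  mi <- sum(joint[nz] * log(joint[nz] / outer(pa, pb)[nz]))
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  denom <- (ha + hb) / 2
  if (denom == 0) return(1)
  min(1, max(0, mi / denom))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement; 1 for identical partitions
#' (up to relabeling), about 0 for random ones. Thin wrapper around
#' [mclust::adjustedRandIndex()].
#'
#' @inheritParams nmi
#' @return ARI in `[-1, 1]`.
#' @export
ari <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  mclust::adjustedRandIndex(a, b)
}

#' Mean silhouette width of a clustering in feature space
#'
#' Average over samples of `(b - a) / max(a, b)` where `a` is the mean
#' Euclidean distance to the sample's own cluster and `b` the mean distance
#' to the nearest other cluster (singleton clusters contribute 0). For
#' multi-omics results pass the concatenated feature matrices
#' (`cbind` of the omics) so cohesion is measured in the original space.
#'
#' @param X Numeric feature matrix, samples in rows.
#' @param labels Cluster labels (at least two distinct clusters).
#' @return Mean silhouette width in `[-1, 1]`.
#' @export
silhouette_score <- function(X, labels) {
  if (length(labels) != nrow(X)) stop("one label per row of X required")
  labels <- as.integer(factor(labels))
  if (length(unique(labels)) < 2L)
    stop("silhouette needs at least two clusters")
  sil <- cluster::silhouette(labels, stats::dist(X))
  mean(sil[, "sil_width"])
}
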