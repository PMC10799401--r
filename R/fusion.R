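#' Per-omic fusion weights from feature counts
#'
#' Each data type gets an unnormalized score `p_i = exp(d_i / sum(d))` from
#' its feature count `d_i`, normalized to weights `w_i = p_i / sum(p)`
#' (a softmax over feature-count fractions). The premise is that a data type
#' carrying more features contributes more information to the integrated
#' network, so weights are strictly increasing in feature count while always
#' remaining positive and summing to one.
#'
#' @param d Positive integer vector of per-omic feature counts (counted after
#'   any feature filtering, i.e. for the matrices actually entering the
#'   affinity step).
#' @return Object of class `"omic_weights"`: list with `d`, `p`
#'   (unnormalized scores) and `w` (weights summing to 1).
#' @examples
#' feature_weights(c(1000, 2000, 5000))$w
#' @export
feature_weights <- function(d) {
  if (length(d) == 0L) stop("empty feature-count vector")
  if (any(d < 1) || any(d != round(d)))
    stop("feature counts must be positive integers")
  d <- as.numeric(d)
  p <- exp(d / sum(d))
  w <- p / sum(p)
  structure(list(d = d, p = p, w = w), class = "omic_weights")
}

#' @export
print.omic_weights <- function(x, ...) {
  cat("omic fusion weights (", length(x$w), " data types)\n", sep = "")
  print(data.frame(features = x$d, weight = signif(x$w, 4)))
  invisible(x)
}

#' Fuse per-omic affinities into one network
#'
#' Weighted linear combination `S = sum_i w_i * A_i` of the per-omic affinity
#' matrices. Because the weights are convex and every affinity has unit
#' diagonal and entries in `[0, 1]`, so does the fused network, and each
#' fused entry lies between the per-omic minimum and maximum.
#'
#' @param affinities List of affinity matrices sharing sample IDs and order
#'   ([local_scaling_affinity()]).
#' @param weights An `"omic_weights"` object ([feature_weights()]) or a
#'   positive numeric vector (normalized to sum to 1), one entry per omic.
#' @return Fused n x n similarity matrix; attribute `"weights"` records the
#'   weights used and `"omics"` the element names of `affinities`.
#' @export
fuse_affinities <- function(affinities, weights) {
  stopifnot(is.list(affinities), length(affinities) >= 1L)
  w <- if (inherits(weights, "omic_weights")) weights$w else as.numeric(weights)
  if (length(w) != length(affinities))
    stop("need one weight per affinity (", length(affinities), " affinities, ",
         length(w), " weights)")
  if (any(w <= 0)) stop("weights must be positive")
  w <- w / sum(w)
  ids <- rownames(affinities[[1L]])
  for (i in seq_along(affinities)) {
    A <- affinities[[i]]
    if (nrow(A) != ncol(A)) stop("affinity ", i, " is not square")
    if (!is.null(ids) && !identical(rownames(A), ids))
      stop("affinity ", i, " has mismatched sample IDs/order; align first")
  }
  S <- matrix(0, nrow(affinities[[1L]]), ncol(affinities[[1L]]))
  for (i in seq_along(affinities)) S <- S + w[i] * affinities[[i]]
  rownames(S) <- colnames(S) <- ids
  attr(S, "weights") <- w
  attr(S, "omics") <- names(affinities)
  S
}
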