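#' Run the full multi-omics subtyping pipeline
#'
#' Orchestrates align -> (optional MAD filter) -> (optional z-scoring) ->
#' per-omic local-scaling affinity -> feature-count weights -> fusion ->
#' self-diffusion -> spectral clustering, with the number of clusters either
#' fixed or estimated from the separation-cost curve. Deterministic given
#' `seed`.
#'
#' @param omics A named list of numeric matrices (samples x features, sample
#'   IDs as row names) or a `"mosd_sim"` object (its `omics` are used).
#'   Matrices without row names are accepted when all have the same number
#'   of rows and are assumed aligned.
#' @param k Neighborhood size for local scales and the diffusion transition
#'   matrix (default 5).
#' @param t Self-diffusion iterations (default 3; 0 skips diffusion).
#' @param alpha Diffusion retention weight (default 0.8).
#' @param n_clusters Integer number of clusters, or `"auto"` (default) to
#'   estimate it with [estimate_cluster_number()].
#' @param c_min,c_max Candidate range for `n_clusters = "auto"` (defaults
#'   2 and 8).
#' @param rule Selection rule for the automatic estimate (`"min"` or
#'   `"largest_drop"`).
#' @param mad_threshold Optional MAD cutoff applied per omic before
#'   scaling (`NULL`, the default, disables filtering).
#' @param standardize Z-score each feature per omic before distances
#'   (default `TRUE`). Disable if the inputs are already on a common scale.
#' @param weights `"auto"` (default: feature-count weights via
#'   [feature_weights()], counted after filtering), `"equal"`, or an
#'   explicit positive numeric vector.
#' @param align Sample alignment policy, `"strict"` (default) or
#'   `"intersect"` (see [align_samples()]).
#' @param seed Integer seed for the k-means step.
#' @return Object of class `"mosd_fit"`: list with `labels` (named integer
#'   vector), `C`, `weights`, `fused` (pre-diffusion network), `diffused`,
#'   `cost_curve` (`NULL` unless `n_clusters = "auto"`), `sample_ids` and
#'   `params`.
#' @examples
#' sim <- simulate_blobs(n_samples = 60, n_groups = 3,
#'                       dims = c(10, 20), separation = 8, seed = 7)
#' fit <- mosd(sim, n_clusters = 3, seed = 7)
#' table(fit$labels, sim$truth)
#' @export
mosd <- function(omics, k = 5L, t = 3L, alpha = 0.8,
                 n_clusters = "auto", c_min = 2L, c_max = 8L,
                 rule = c("min", "largest_drop"),
                 mad_threshold = NULL, standardize = TRUE,
                 weights = "auto", align = c("strict", "intersect"),
                 seed = 1L) {
  rule <- match.arg(rule)
  align <- match.arg(align)
  if (inherits(omics, "mosd_sim")) omics <- omics$omics
  stopifnot(is.list(omics), length(omics) >= 1L)
  omics <- lapply(omics, as.matrix)
  if (is.null(names(omics)))
    names(omics) <- sprintf("omic%d", seq_along(omics))

  no_ids <- vapply(omics, function(m) is.null(rownames(m)), logical(1L))
  if (all(no_ids)) {
    ns <- vapply(omics, nrow, integer(1L))
    if (length(unique(ns)) != 1L)
      stop("omics without sample IDs must have equal row counts")
    for (i in seq_along(omics))
      rownames(omics[[i]]) <- sprintf("S%03d", seq_len(ns[1L]))
  } else if (any(no_ids)) {
    stop("either all omics or none must carry sample IDs (rownames)")
  }
  omics <- align_samples(omics, policy = align)
  ids <- rownames(omics[[1L]])
  n <- length(ids)
  if (n < 3L) stop("need at least 3 aligned samples")

  if (!is.null(mad_threshold))
    omics <- lapply(omics, mad_filter, threshold = mad_threshold)
  if (isTRUE(standardize))
    omics <- lapply(omics, standardize_features)

  d_counts <- vapply(omics, ncol, integer(1L))
  w <- if (identical(weights, "auto")) {
    feature_weights(d_counts)
  } else if (identical(weights, "equal")) {
    feature_weights(rep(1L, length(omics)))
  } else {
    as.numeric(weights)
  }

  affinities <- lapply(omics, local_scaling_affinity, k = k)
  S <- fuse_affinities(affinities, w)
  Sd <- self_diffuse(S, knn = k, alpha = alpha, t = t)

  cost_curve <- NULL
  if (identical(n_clusters, "auto")) {
    cost_curve <- estimate_cluster_number(Sd, c_min = c_min, c_max = c_max,
                                          rule = rule)
    C <- cost_curve$chosen
  } else {
    C <- as.integer(n_clusters)
  }
  labels <- spectral_cluster(Sd, C, seed = seed)

  structure(list(labels = labels, C = C,
                 weights = attr(S, "weights"),
                 fused = S, diffused = Sd, cost_curve = cost_curve,
                 sample_ids = ids,
                 params = list(k = as.integer(k), t = as.integer(t),
                               alpha = alpha, n_clusters = n_clusters,
                               c_min = c_min, c_max = c_max, rule = rule,
                               mad_threshold = mad_threshold,
                               standardize = standardize,
                               weights = weights, align = align,
                               seed = as.integer(seed),
                               d_features = d_counts)),
            class = "mosd_fit")
}

#' @export
print.mosd_fit <- function(x, ...) {
  cat("mosd fit: ", length(x$labels), " samples in ", x$C, " clusters\n",
      sep = "")
  cat("  cluster sizes:", paste(tabulate(x$labels, x$C), collapse = ", "), "\n")
  cat("  omic weights:",
      paste(sprintf("%s=%.3f", names(x$params$d_features), x$weights),
            collapse = ", "), "\n")
  cat("  k =", x$params$k, " t =", x$params$t, " alpha =", x$params$alpha,
      " seed =", x$params$seed, "\n")
  if (!is.null(x$cost_curve))
    cat("  C chosen by separation cost (rule '", x$cost_curve$rule, "')\n",
        sep = "")
  invisible(x)
}
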