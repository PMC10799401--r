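# Shared (memoized) neighborhood- and iteration-sweep NMI curves on the
# simulated ten-group three-omic benchmark; used by several acceptance
# checks, computed once per test run.

.sweep_cache <- new.env(parent = emptyenv())

benchmark_sweeps <- function(seeds = 1:3) {
  key <- paste0("s", paste(seeds, collapse = "_"))
  if (!is.null(.sweep_cache[[key]])) return(.sweep_cache[[key]])
  ks <- 2:15
  ts <- c(0, 2:15)
  nmi_k <- matrix(NA_real_, length(ks), length(seeds))
  nmi_t <- matrix(NA_real_, length(ts), length(seeds))
  for (j in seq_along(seeds)) {
    seed <- seeds[j]
    sim <- simulate_counts(seed = seed)     # study defaults: 500 x 10 groups
    om <- lapply(sim$omics, normalize_counts)
    dist_m <- lapply(om, pairwise_distances)
    fw <- feature_weights(vapply(om, ncol, integer(1L)))
    for (i in seq_along(ks)) {
      affs <- lapply(dist_m, affinity_from_distances, k = ks[i])
      S <- fuse_affinities(affs, fw)
      Sd <- self_diffuse(S, knn = ks[i], alpha = 0.8, t = 3)
      nmi_k[i, j] <- nmi(spectral_cluster(Sd, 10, seed = seed), sim$truth)
    }
    affs5 <- lapply(dist_m, affinity_from_distances, k = 5)
    S5 <- fuse_affinities(affs5, fw)
    for (i in seq_along(ts)) {
      Sd <- self_diffuse(S5, knn = 5, alpha = 0.8, t = ts[i])
      nmi_t[i, j] <- nmi(spectral_cluster(Sd, 10, seed = seed), sim$truth)
    }
  }
  out <- list(ks = ks, ts = ts,
              nmi_k = rowMeans(nmi_k), nmi_t = rowMeans(nmi_t))
  .sweep_cache[[key]] <- out
  out
}
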