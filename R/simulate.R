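# Synthetic multi-omics cohorts with known group labels. Two generators:
# a grouped negative-binomial count simulator in the style of scRNA-seq
# simulators (log-normal gene means, per-group differential-expression
# factors, log-normal library sizes, NB noise), and fast Gaussian blobs for
# unit tests.

#' Simulate grouped negative-binomial count omics
#'
#' Generates `length(genes_per_omic)` count matrices over one shared sample
#' set split into `n_groups` equiprobable groups. Per omic and gene, a base
#' mean is drawn log-normally; for each group, a `de_prob` fraction of genes
#' receives a multiplicative differential-expression factor
#' `exp(+/- N(de_fold, de_fold / 2))` (direction up or down with equal
#' probability); each sample's expected profile is the group's mean profile
#' rescaled to a log-normal library size; counts are negative binomial with
#' dispersion `dispersion` (variance `mu + dispersion * mu^2`). Omics share
#' the group labels but draw genes, factors and noise independently.
#'
#' Group distinctness is graded: group g's DE fraction is `de_prob`
#' multiplied by the g-th value of `seq(de_prob_spread[1],
#' de_prob_spread[2])`, so some groups are crisply separated while others
#' blend into the background — the mixture of easy and hard groups that
#' makes recovery partial rather than all-or-nothing, as in real cohorts.
#' Defaults emulate a ten-group, 500-sample, three-omic (1000/2000/5000
#' gene) single-cell-style benchmark whose groups are only partially
#' recoverable.
#'
#' @param n_samples Number of samples (default 500).
#' @param n_groups Number of groups (default 10), assigned uniformly at
#'   random; assignments are redrawn (up to 100 times) until every group has
#'   at least 2 samples.
#' @param genes_per_omic Integer vector of gene counts, one per omic
#'   (default `c(1000, 2000, 5000)`).
#' @param de_prob Mean fraction of genes differentially expressed per group
#'   (default 0.1).
#' @param de_fold Location of the log-scale DE factor (default 0.65);
#'   larger values separate the groups more.
#' @param de_prob_spread Length-2 multiplier range grading per-group DE
#'   fractions from weakest to strongest group (default `c(0.15, 1.85)`,
#'   mean 1 so `de_prob` is preserved on average); use `c(1, 1)` for
#'   equally distinct groups.
#' @param lib_loc,lib_scale Meanlog / sdlog of the log-normal library sizes
#'   (defaults 11 and 0.2).
#' @param dispersion NB dispersion phi, variance `mu + phi mu^2`
#'   (default 0.9).
#' @param mean_log,mean_sd Meanlog / sdlog of the log-normal gene base means
#'   (defaults 0 and 1); only their shape matters because profiles are
#'   renormalized to library size.
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return Object of class `"mosd_sim"`: list with `omics` (named list of
#'   sample x gene count matrices), `truth` (integer group labels named by
#'   sample ID) and `params`.
#' @seealso [simulate_blobs()], [normalize_counts()]
#' @export
simulate_counts <- function(n_samples = 500L, n_groups = 10L,
                            genes_per_omic = c(1000L, 2000L, 5000L),
                            de_prob = 0.1, de_fold = 0.65,
                            de_prob_spread = c(0.15, 1.85),
                            lib_loc = 11, lib_scale = 0.2,
                            dispersion = 0.9,
                            mean_log = 0, mean_sd = 1,
                            seed = 1L) {
  stopifnot(n_groups <= n_samples, de_prob > 0, de_prob <= 1,
            all(genes_per_omic >= 1), dispersion >= 0,
            length(de_prob_spread) == 2L, all(de_prob_spread >= 0))
  group_probs <- pmin(1, de_prob * seq(de_prob_spread[1L], de_prob_spread[2L],
                                       length.out = n_groups))
  withr::with_seed(as.integer(seed), {
    truth <- resample_groups(n_samples, n_groups)
    ids <- sprintf("S%03d", seq_len(n_samples))
    names(truth) <- ids
    omics <- vector("list", length(genes_per_omic))
    for (m in seq_along(genes_per_omic)) {
      d <- as.integer(genes_per_omic[m])
      base <- stats::rlnorm(d, meanlog = mean_log, sdlog = mean_sd)
      # per-group mean profiles: base means times DE factors
      group_means <- matrix(rep(base, n_groups), nrow = n_groups, byrow = TRUE)
      for (g in seq_len(n_groups)) {
        is_de <- stats::runif(d) < group_probs[g]
        n_de <- sum(is_de)
        if (n_de > 0L) {
          lf <- stats::rnorm(n_de, mean = de_fold, sd = de_fold / 2)
          sign <- ifelse(stats::runif(n_de) < 0.5, -1, 1)
          group_means[g, is_de] <- group_means[g, is_de] * exp(sign * lf)
        }
      }
      lib <- stats::rlnorm(n_samples, meanlog = lib_loc, sdlog = lib_scale)
      prof <- group_means / rowSums(group_means)   # relative abundances
      mu <- prof[truth, , drop = FALSE] * lib
      size <- if (dispersion > 0) 1 / dispersion else Inf
      counts <- matrix(stats::rnbinom(n_samples * d, mu = mu, size = size),
                       nrow = n_samples,
                       dimnames = list(ids, sprintf("G%05d", seq_len(d))))
      omics[[m]] <- counts
    }
    names(omics) <- sprintf("omic%d", seq_along(omics))
    structure(list(omics = omics, truth = truth,
                   params = list(n_samples = n_samples, n_groups = n_groups,
                                 genes_per_omic = genes_per_omic,
                                 de_prob = de_prob, de_fold = de_fold,
                                 de_prob_spread = de_prob_spread,
                                 group_probs = group_probs,
                                 lib_loc = lib_loc, lib_scale = lib_scale,
                                 dispersion = dispersion, seed = seed)),
              class = "mosd_sim")
  })
}

resample_groups <- function(n_samples, n_groups) {
  for (try in seq_len(100L)) {
    g <- sample.int(n_groups, n_samples, replace = TRUE)
    if (all(tabulate(g, n_groups) >= 2L)) return(g)
  }
  stop("could not draw a group assignment with every group of size >= 2")
}

#' Simulate Gaussian-blob multi-omics data
#'
#' Fast, fully controllable fixture: each omic places the `n_groups` group
#' centers `separation` apart (centers `separation / sqrt(2)` along distinct
#' coordinate axes, so every pair of centers is exactly `separation` apart)
#' and adds unit-variance Gaussian noise. `separation = 0` gives a single
#' blob with unrecoverable labels.
#'
#' @param n_samples Number of samples.
#' @param n_groups Number of groups (each needs `>= 2` samples).
#' @param dims Integer vector of feature counts per omic; each must be
#'   `>= n_groups`.
#' @param separation Distance between any two group centers (default 6).
#' @param seed Integer seed.
#' @return Object of class `"mosd_sim"` (see [simulate_counts()]).
#' @export
simulate_blobs <- function(n_samples, n_groups, dims, separation = 6,
                           seed = 1L) {
  stopifnot(separation >= 0, n_groups <= n_samples)
  if (any(dims < n_groups))
    stop("every omic needs at least n_groups features for the center layout")
  withr::with_seed(as.integer(seed), {
    truth <- resample_groups(n_samples, n_groups)
    ids <- sprintf("S%03d", seq_len(n_samples))
    names(truth) <- ids
    omics <- lapply(seq_along(dims), function(m) {
      d <- as.integer(dims[m])
      centers <- matrix(0, n_groups, d)
      centers[cbind(seq_len(n_groups), seq_len(n_groups))] <- separation / sqrt(2)
      X <- centers[truth, , drop = FALSE] +
        matrix(stats::rnorm(n_samples * d), n_samples, d)
      dimnames(X) <- list(ids, sprintf("F%04d", seq_len(d)))
      X
    })
    names(omics) <- sprintf("omic%d", seq_along(omics))
    structure(list(omics = omics, truth = truth,
                   params = list(n_samples = n_samples, n_groups = n_groups,
                                 dims = dims, separation = separation,
                                 seed = seed)),
              class = "mosd_sim")
  })
}

#' @export
print.mosd_sim <- function(x, ...) {
  cat("synthetic multi-omics dataset: ", length(x$truth), " samples, ",
      length(unique(x$truth)), " groups, ", length(x$omics), " omic(s) (",
      paste(vapply(x$omics, ncol, integer(1L)), collapse = "/"),
      " features)\n", sep = "")
  invisible(x)
}
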