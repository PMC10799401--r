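#' Load a samples-by-features omics matrix from delimited text
#'
#' Reads a TSV/CSV file with one header row and one leading ID column into a
#' numeric matrix with sample IDs as row names and feature IDs as column
#' names. Files whose extension is `.csv` are read comma-separated, anything
#' else tab-separated (override with `sep`).
#'
#' @param path Path to the delimited text file.
#' @param orientation `"samples_in_rows"` (default) if rows are samples, or
#'   `"samples_in_cols"` if the file stores features in rows; the returned
#'   matrix always has samples in rows.
#' @param sep Field separator; `NULL` (default) picks by file extension.
#' @param name Optional omic label stored as the `"omic"` attribute.
#' @return Numeric matrix (n samples x d features) with unique sample IDs as
#'   row names.
#' @details Missing or non-numeric cells are rejected with an error naming
#'   the offending sample and feature; impute upstream if needed. At least
#'   3 samples and 2 features are required.
#' @seealso [write_omics_matrix()], [align_samples()]
#' @export
load_omics_matrix <- function(path,
                              orientation = c("samples_in_rows", "samples_in_cols"),
                              sep = NULL, name = NULL) {
  orientation <- match.arg(orientation)
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("file must have an ID column plus at least one data column: ", path)
  ids <- df[[1L]]
  body <- as.matrix(df[, -1L, drop = FALSE])
  X <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body),
                               dimnames = list(ids, colnames(body))))
  bad <- which(is.na(X), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric or missing value at row '%s', column '%s' in %s",
                 rownames(X)[bad[1L, 1L]], colnames(X)[bad[1L, 2L]], path))
  }
  if (orientation == "samples_in_cols") X <- t(X)
  if (anyDuplicated(rownames(X)))
    stop("duplicate sample IDs: ",
         paste(unique(rownames(X)[duplicated(rownames(X))]), collapse = ", "))
  if (nrow(X) < 3L) stop("need at least 3 samples, got ", nrow(X))
  if (ncol(X) < 2L) stop("need at least 2 features, got ", ncol(X))
  if (!is.null(name)) attr(X, "omic") <- name
  X
}

#' Write an omics matrix (or any matrix with sample IDs) as delimited text
#'
#' Inverse of [load_omics_matrix()]: writes a header row of feature IDs and a
#' first column of sample IDs. Square similarity matrices are written the
#' same way with sample IDs on both axes.
#'
#' @param X Numeric matrix with row names.
#' @param path Output path. `.csv` extension writes comma-separated.
#' @param id_col Name of the leading ID column (default `"sample_id"`).
#' @export
write_omics_matrix <- function(X, path, id_col = "sample_id") {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(rownames(X), X, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write cluster labels as a two-column table
#'
#' @param labels Integer vector of cluster assignments, named by sample ID
#'   (or supply `sample_ids`).
#' @param path Output path (TSV).
#' @param sample_ids Optional sample IDs overriding `names(labels)`.
#' @export
write_cluster_labels <- function(labels, path, sample_ids = names(labels)) {
  if (is.null(sample_ids)) sample_ids <- seq_along(labels)
  df <- data.frame(sample_id = sample_ids, cluster = as.integer(labels))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align several omics matrices onto a shared, identically ordered sample set
#'
#' The fusion step requires every omic to describe the same samples in the
#' same order. `policy = "strict"` (default) demands identical sample sets
#' and reorders all omics to the first omic's order; `policy = "intersect"`
#' keeps the common samples only (in the first omic's order) and reports how
#' many samples each omic dropped.
#'
#' @param omics List of numeric matrices, samples in rows, row names set.
#' @param policy `"strict"` or `"intersect"`.
#' @return List of matrices with identical `rownames` in identical order.
#' @export
align_samples <- function(omics, policy = c("strict", "intersect")) {
  policy <- match.arg(policy)
  stopifnot(is.list(omics), length(omics) >= 1L)
  for (i in seq_along(omics)) {
    if (is.null(rownames(omics[[i]])))
      stop("omic ", i, " has no sample IDs (rownames)")
  }
  ref <- rownames(omics[[1L]])
  common <- ref
  for (m in omics[-1L]) common <- common[common %in% rownames(m)]
  if (policy == "strict") {
    for (i in seq_along(omics)) {
      if (!setequal(rownames(omics[[i]]), ref))
        stop("omic ", i, " has a different sample set; use policy = 'intersect'")
    }
    common <- ref
  }
  if (length(common) == 0L) stop("no samples shared across all omics")
  out <- lapply(omics, function(m) m[common, , drop = FALSE])
  dropped <- vapply(omics, function(m) nrow(m) - length(common), integer(1L))
  if (any(dropped > 0L))
    message("align_samples: dropped ", paste(dropped, collapse = "/"),
            " samples per omic; ", length(common), " retained")
  names(out) <- names(omics)
  out
}

#' Filter features by median absolute deviation
#'
#' Keeps exactly the features whose raw median absolute deviation across
#' samples (median of absolute deviations from the feature median, no
#' consistency constant) is strictly greater than `threshold`. Used to enrich
#' for variable, informative features before building affinities.
#'
#' @param X Numeric matrix, samples in rows.
#' @param threshold Non-negative MAD cutoff; a feature is kept iff
#'   `MAD > threshold`.
#' @return `X` restricted to the retained features; samples unchanged.
#' @export
mad_filter <- function(X, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold >= 0)
  mads <- apply(X, 2L, stats::mad, constant = 1)
  keep <- mads > threshold
  if (!any(keep))
    stop("MAD filter removed every feature; lower the threshold (max MAD = ",
         format(max(mads)), ")")
  X[, keep, drop = FALSE]
}

#' Z-score each feature
#'
#' Centers every feature to mean zero and scales to unit standard deviation
#' (sample sd, denominator n - 1). Constant features carry no distance
#' information and cannot be scaled; they are dropped with a warning.
#'
#' @param X Numeric matrix, samples in rows.
#' @return Matrix of the same samples with standardized (non-constant)
#'   features.
#' @export
standardize_features <- function(X) {
  sds <- apply(X, 2L, stats::sd)
  const <- sds == 0 | !is.finite(sds)
  if (any(const)) {
    warning("dropping ", sum(const), " constant feature(s) before scaling")
    X <- X[, !const, drop = FALSE]
    sds <- sds[!const]
  }
  if (ncol(X) == 0L) stop("all features constant; nothing to standardize")
  ctr <- colMeans(X)
  out <- sweep(sweep(X, 2L, ctr, "-"), 2L, sds, "/")
  out
}

#' Log-transform and z-score a count matrix
#'
#' Convenience preprocessing for count data entering the affinity step:
#' `log1p` to tame the mean-variance trend, then per-feature z-scoring so no
#' feature dominates the Euclidean distances.
#'
#' @param counts Non-negative count matrix, samples in rows.
#' @return Standardized `log1p` matrix.
#' @export
normalize_counts <- function(counts) {
  standardize_features(log1p(counts))
}
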