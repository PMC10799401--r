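write_tsv_fixture <- function(mat, ids, features, path = tempfile(fileext = ".tsv")) {
  df <- data.frame(sample_id = ids, mat, check.names = FALSE)
  colnames(df)[-1] <- features
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("delimited matrices load with both orientations and round-trip", {
  X <- matrix(c(0, 0, 0, 0, 0, 0), nrow = 3)
  p <- write_tsv_fixture(X, c("a", "b", "c"), c("f1", "f2"))
  m <- load_omics_matrix(p)
  expect_identical(dim(m), c(3L, 2L))
  expect_true(all(m == 0))
  expect_identical(rownames(m), c("a", "b", "c"))

  # features-in-rows file transposes back to the same matrix
  Y <- matrix(rnorm(12), nrow = 4,
              dimnames = list(letters[1:4], c("g1", "g2", "g3")))
  p2 <- write_tsv_fixture(Y, rownames(Y), colnames(Y))
  p3 <- write_tsv_fixture(t(Y), colnames(Y), rownames(Y))
  expect_equal(load_omics_matrix(p3, orientation = "samples_in_cols"),
               load_omics_matrix(p2), tolerance = 1e-12)

  # write -> load reproduces values at full printed precision
  p4 <- tempfile(fileext = ".tsv")
  write_omics_matrix(load_omics_matrix(p2), p4)
  expect_equal(load_omics_matrix(p4), load_omics_matrix(p2), tolerance = 1e-12)
})

test_that("missing cells and duplicate sample IDs are rejected with coordinates", {
  df <- data.frame(sample_id = c("a", "b", "c"),
                   f1 = c("1", "NA", "3"), f2 = c("4", "5", "6"))
  p <- tempfile(fileext = ".tsv")
  write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_omics_matrix(p), "'b'.*'f1'")

  df2 <- data.frame(sample_id = c("a", "a", "c"),
                    f1 = c("1", "2", "3"), f2 = c("4", "5", "6"))
  p2 <- tempfile(fileext = ".tsv")
  write.table(df2, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_omics_matrix(p2), "duplicate")
})

test_that("sample alignment reorders, intersects, and rejects disjoint sets", {
  A <- matrix(1:6, 3, 2, dimnames = list(c("a", "b", "c"), NULL))
  B <- matrix(1:6, 3, 2, dimnames = list(c("c", "a", "b"), NULL))
  out <- align_samples(list(A, B), policy = "strict")
  expect_identical(rownames(out[[2]]), c("a", "b", "c"))
  expect_identical(out[[1]], A)  # strict is a no-op when already aligned

  C <- matrix(1:6, 3, 2, dimnames = list(c("b", "c", "d"), NULL))
  expect_error(align_samples(list(A, C), policy = "strict"), "different sample set")
  suppressMessages(ints <- align_samples(list(A, C), policy = "intersect"))
  expect_identical(rownames(ints[[1]]), c("b", "c"))
  expect_identical(rownames(ints[[2]]), c("b", "c"))

  D <- matrix(1:2, 1, 2, dimnames = list("z", NULL))
  expect_error(align_samples(list(A, D), policy = "intersect"), "no samples shared")
})

test_that("MAD filter keeps exactly the features above threshold and is idempotent", {
  X <- cbind(const = rep(2, 5), ramp = 0:4, tiny = c(0, 0.1, 0.2, 0.3, 0))
  # median absolute deviation of 0:4 is 1.0 > 0.5; constant is 0
  kept <- mad_filter(X, 0.5)
  expect_identical(colnames(kept), "ramp")
  expect_identical(nrow(kept), 5L)
  expect_identical(mad_filter(kept, 0.5), kept)

  # threshold 0 removes constants only
  expect_identical(colnames(mad_filter(X, 0)), c("ramp", "tiny"))
  # column order does not affect which features survive
  expect_identical(sort(colnames(mad_filter(X[, 3:1], 0))),
                   sort(colnames(mad_filter(X, 0))))
  expect_error(mad_filter(X, 100), "lower the threshold")
})

test_that("feature standardization centers and scales (sample sd) and is idempotent", {
  X <- cbind(a = c(1, 2, 3), b = c(10, 0, 5))
  Z <- standardize_features(X)
  expect_equal(Z[, "a"], c(-1, 0, 1), ignore_attr = TRUE)
  expect_equal(colMeans(Z), c(a = 0, b = 0), tolerance = 1e-12)
  expect_equal(apply(Z, 2, sd), c(a = 1, b = 1), tolerance = 1e-12)
  expect_equal(standardize_features(Z), Z, tolerance = 1e-12)
  expect_warning(standardize_features(cbind(X, k = rep(7, 3))), "constant")
})
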