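test_that("median-of-ratios recovers known cell scalings", {
  set.seed(31)
  base <- matrix(rpois(200 * 8, 50) + 1, 200, 8)  # all positive
  scale <- c(0.5, 1, 2, 1, 0.8, 1.25, 1, 1)
  counts <- sweep(base, 2, scale, "*")
  sf <- median_ratio_size_factors(counts)
  expect_equal(exp(mean(log(sf))), 1)
  # recovered factors proportional to the true scalings
  expect_equal(sf / exp(mean(log(scale))), scale / exp(mean(log(scale))),
               tolerance = 0.05, ignore_attr = TRUE)
})

test_that("median-of-ratios agrees with the DESeq2 implementation", {
  set.seed(32)
  # odd gene count: the per-cell median is a single ratio, so the two
  # implementations (median of ratios vs exp of median log ratio) coincide
  counts <- matrix(rpois(301 * 10, 40) + 1, 301, 10)
  sf <- median_ratio_size_factors(counts)
  ref <- DESeq2::estimateSizeFactorsForMatrix(counts)
  expect_equal(sf / exp(mean(log(sf))), ref / exp(mean(log(ref))),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("ratio type errors without an all-positive gene; poscounts works", {
  counts <- rbind(c(0, 5, 8, 3), c(4, 0, 7, 2), c(9, 3, 0, 1))
  expect_error(median_ratio_size_factors(counts), "poscounts")
  sf <- median_ratio_size_factors(counts, type = "poscounts")
  expect_length(sf, 4)
  expect_true(all(sf > 0))
  expect_equal(exp(mean(log(sf))), 1)
})

test_that("detection filter requires the rate in both conditions", {
  cond <- rep(1:2, each = 8)
  counts <- rbind(
    both    = rep(5, 16),                       # detected everywhere
    onesided = c(rep(5, 8), rep(0, 7), 5),      # 100% vs 12.5%
    neither = rep(0, 16)
  )
  expect_equal(detection_filter(counts, cond, 0.25), "both")
  expect_equal(detection_filter(counts, cond, 0.1),
               c("both", "onesided"))
})

test_that("gene views expose log nonzero values and the zero pattern", {
  counts <- rbind(g1 = c(0, 2, 4, 0, 8, 16), g2 = c(1, 1, 1, 1, 1, 1))
  cond <- rep(1:2, each = 3)
  views <- make_gene_views(counts, cond)
  expect_named(views, c("g1", "g2"))
  v <- views$g1
  expect_equal(v$zero_flag, c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE),
               ignore_attr = TRUE)
  expect_equal(v$nonzero_log, log(c(2, 4, 8, 16)), ignore_attr = TRUE)
  expect_equal(v$condition, cond)
  expect_true(v$testable)
  v2 <- make_gene_views(counts, cond, log_base = 2)$g1
  expect_equal(v2$nonzero_log, c(1, 2, 3, 4), ignore_attr = TRUE)
})

test_that("the detection covariate is the per-cell nonzero fraction", {
  counts <- rbind(c(0, 2, 4, 4), c(3, 0, 5, 1))
  views <- make_gene_views(counts, c(1, 1, 2, 2), covariate = "detection")
  expect_equal(views[[1]]$covariate, c(0.5, 0.5, 1, 1), ignore_attr = TRUE)
})

test_that("untestable genes are flagged in views", {
  counts <- rbind(c(2, 3, 0, 0), c(2, 3, 0, 4))
  views <- make_gene_views(counts, c(1, 1, 2, 2))
  expect_false(views[[1]]$testable)
  expect_true(views[[2]]$testable)
})

test_that("delimited and matrix-market readers round-trip a matrix", {
  m <- matrix(c(0, 3, 7, 2, 0, 9), 2, 3,
              dimnames = list(c("gA", "gB"), c("c1", "c2", "c3")))
  tsv <- tempfile(fileext = ".tsv")
  write.table(m, tsv, sep = "\t", quote = FALSE, col.names = NA)
  expect_equal(read_counts(tsv), m)

  mtx <- tempfile(fileext = ".mtx")
  Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), mtx)
  writeLines(rownames(m), sub("\\.mtx$", ".rownames", mtx))
  writeLines(colnames(m), sub("\\.mtx$", ".colnames", mtx))
  expect_equal(read_counts(mtx), m)
})

test_that("input validation rejects malformed matrices and conditions", {
  expect_error(median_ratio_size_factors(matrix(c(-1, 2, 3, 4), 2)),
               "non-negative")
  expect_error(make_gene_views(matrix(1:6, 2), c(1, 2)), "one label per cell")
  expect_error(make_gene_views(matrix(1:4, 2), c(1, 1)), "two conditions")
  expect_error(detection_filter(matrix(1:4, 2), c(1, 1), 0.25),
               "two conditions")
})
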