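test_that("the permutation p-value uses the add-one estimator", {
  set.seed(41)
  v <- make_test_view(rnorm(25, 1, 0.5), rnorm(25, 1.4, 0.5))
  res <- permutation_test(v, n_perm = 60, seed = 5)
  expect_length(res$perm_scores, 60)
  expect_equal(res$p_perm,
               (1 + sum(res$perm_scores >= res$score)) / 61)
  expect_gte(res$p_perm, 1 / 61)
  expect_lte(res$p_perm, 1)
  # reproducible under the same seed
  res2 <- permutation_test(v, n_perm = 60, seed = 5)
  expect_equal(res$perm_scores, res2$perm_scores)
  expect_equal(res$score, res2$score)
})

test_that("a strongly shifted gene is detected, a null gene is not extreme", {
  set.seed(42)
  de <- make_test_view(rnorm(40, 1, 0.4), rnorm(40, 4, 0.4))
  res <- permutation_test(de, n_perm = 99, seed = 1)
  expect_equal(res$p_perm, 1 / 100)  # observed beats every permutation

  null <- make_test_view(rnorm(40, 2, 0.5), rnorm(40, 2, 0.5))
  res0 <- permutation_test(null, n_perm = 99, seed = 1)
  expect_gt(res0$p_perm, 0.05)
})

test_that("genes with too few nonzero cells in a condition are untestable", {
  v <- list(nonzero_log = c(1, 1.2, 0.9, 2),
            zero_flag = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE),
            condition = c(1, 1, 1, 2, 2, 2),
            covariate = NULL, testable = TRUE)
  res <- permutation_test(v, n_perm = 10)
  expect_false(res$testable)
  expect_true(is.na(res$score))
  expect_true(is.na(res$p_perm))
})

test_that("permutations preserve the zero pattern and condition sizes", {
  # with zeroes attached to cells, permuted conditions can have varying
  # numbers of nonzero cells but fixed total size; the observed score of a
  # view must not depend on cell order within conditions
  set.seed(43)
  y1 <- rnorm(20, 2, 0.5)
  y2 <- rnorm(20, 2, 0.5)
  v <- make_test_view(y1, y2)
  vs <- make_test_view(sample(y1), sample(y2))
  r1 <- permutation_test(v, n_perm = 5, seed = 2)
  r2 <- permutation_test(vs, n_perm = 5, seed = 2)
  expect_equal(r1$score, r2$score)
})

test_that("residual permutation preserves fitted values plus residual set", {
  set.seed(44)
  n <- 30
  covar <- runif(2 * n)
  y <- 1 + 2 * covar + rnorm(2 * n, 0, 0.1)
  v <- list(nonzero_log = y, zero_flag = rep(FALSE, 2 * n),
            condition = rep(1:2, each = n), covariate = covar,
            testable = TRUE)
  perm <- residual_permutation_values(v, seed = 9)
  fit <- lm(y ~ covar)
  expect_equal(sort(perm - fitted(fit)), sort(residuals(fit)),
               ignore_attr = TRUE)
  # covariate path of the permutation test runs and returns a p-value
  res <- permutation_test(v, n_perm = 20, seed = 3)
  expect_true(res$testable)
  expect_true(res$p_perm > 0 && res$p_perm <= 1)
})

test_that("a constant covariate falls back to plain permutation", {
  set.seed(45)
  v <- make_test_view(rnorm(20), rnorm(20))
  v$covariate <- rep(1, 40)
  expect_warning(res <- permutation_test(v, n_perm = 10, seed = 1),
                 "constant covariate")
  expect_true(res$testable)
})

test_that("bh_adjust matches the independent step-up oracle", {
  set.seed(46)
  for (i in 1:5) {
    p <- runif(50)^2
    expect_equal(bh_adjust(p), oracle_bh(p))
  }
  expect_equal(bh_adjust(numeric()), numeric())
})

test_that("mean-shift rescue flags shifted genes only", {
  set.seed(47)
  genes <- list(
    shifted = make_test_view(rnorm(30, 1, 0.3), rnorm(30, 2.5, 0.3)),
    null = make_test_view(rnorm(30, 1, 0.3), rnorm(30, 1, 0.3))
  )
  out <- mean_shift_rescue(genes, fdr_target = 0.05)
  expect_equal(out$gene, c("shifted", "null"))
  expect_true(out$rescued[1])
  expect_false(out$rescued[2])
  expect_equal(out$t_p[1],
               t.test(genes$shifted$nonzero_log[1:30],
                      genes$shifted$nonzero_log[31:60])$p.value,
               ignore_attr = TRUE)
})

test_that("Fisher rescue requires matching component counts and skew", {
  set.seed(48)
  # DP pattern: same two modes, opposite proportions
  y1 <- c(rnorm(8, 1, 0.3), rnorm(32, 5, 0.3))
  y2 <- c(rnorm(32, 1, 0.3), rnorm(8, 5, 0.3))
  v <- make_test_view(y1, y2)
  z1 <- estimate_partition(y1)
  z2 <- estimate_partition(y2)
  zp <- estimate_partition(c(y1, y2))
  expect_true(fisher_dp_rescue(v, z1, z2, zp))

  # balanced proportions: not rescued
  y1b <- c(rnorm(20, 1, 0.3), rnorm(20, 5, 0.3))
  y2b <- c(rnorm(20, 1, 0.3), rnorm(20, 5, 0.3))
  vb <- make_test_view(y1b, y2b)
  expect_false(fisher_dp_rescue(vb, estimate_partition(y1b),
                                estimate_partition(y2b),
                                estimate_partition(c(y1b, y2b))))

  # unimodal everywhere: c_oa < 2, no rescue
  yu <- rnorm(40, 2, 0.4)
  vu <- make_test_view(yu[1:20], yu[21:40])
  expect_false(fisher_dp_rescue(vu, estimate_partition(yu[1:20]),
                                estimate_partition(yu[21:40]),
                                estimate_partition(yu)))
})
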