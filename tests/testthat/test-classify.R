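test_that("component_summary orders components by mean and filters size", {
  set.seed(51)
  y1 <- c(rnorm(20, 5, 0.3), rnorm(20, 1, 0.3))  # high mode listed first
  y2 <- rnorm(40, 3, 0.3)
  v <- make_test_view(y1, y2)
  z1 <- new_partition(rep(1:2, each = 20))
  z2 <- new_partition(rep(1, 40))
  zp <- new_partition(c(rep(1:2, each = 20), rep(3, 40)))
  cs <- component_summary(v, z1, z2, zp)
  expect_s3_class(cs, "component_summary")
  expect_equal(cs$c1, 2L)
  expect_equal(cs$c2, 1L)
  expect_equal(cs$c_oa, 3L)
  expect_true(all(diff(cs$cond1$means) > 0))  # mean-ordered
  expect_equal(cs$cond1$proportions, c(0.5, 0.5))

  # a 2-cell component is not counted
  z1b <- new_partition(rep(1:2, c(38, 2)))
  csb <- component_summary(v, z1b, z2, zp)
  expect_equal(csb$c1, 1L)
})

test_that("posterior overlap is true for identical and false for distant", {
  pr <- ng_prior()
  near <- ng_posterior_params(rnorm(30, 2, 0.3), pr)
  far <- ng_posterior_params(rnorm(30, 9, 0.3), pr)
  expect_true(component_overlap(near, near, seed = 1))
  expect_false(component_overlap(near, far, seed = 1))
})

test_that("classification rules reproduce the four canonical patterns", {
  # rule-level check: partitions are the generative ones, so only the
  # category decision logic is under test here (estimation is tested
  # elsewhere)
  set.seed(52)
  classify_known <- function(y1, y2, l1, l2, lp) {
    v <- make_test_view(y1, y2)
    cs <- component_summary(v, new_partition(l1), new_partition(l2),
                            new_partition(lp))
    classify_dd_gene(cs, seed = 1)
  }
  # DE: one shifted component per condition
  expect_equal(classify_known(rnorm(50, 2, 0.3), rnorm(50, 5, 0.3),
                              rep(1, 50), rep(1, 50), rep(1:2, each = 50)),
               "DE")
  # DP: shared modes, opposite proportions
  expect_equal(classify_known(c(rnorm(10, 2, 0.3), rnorm(40, 6, 0.3)),
                              c(rnorm(40, 2, 0.3), rnorm(10, 6, 0.3)),
                              rep(1:2, c(10, 40)), rep(1:2, c(40, 10)),
                              rep(c(1, 2, 1, 2), c(10, 40, 40, 10))),
               "DP")
  # DM: unimodal condition 1 matching the low mode of condition 2
  expect_equal(classify_known(rnorm(50, 2, 0.3),
                              c(rnorm(25, 2, 0.3), rnorm(25, 6, 0.3)),
                              rep(1, 50), rep(1:2, each = 25),
                              rep(c(1, 1, 2), c(50, 25, 25))),
               "DM")
  # DB: unimodal condition 1 centred between the condition-2 modes
  expect_equal(classify_known(rnorm(50, 4, 0.3),
                              c(rnorm(25, 2, 0.3), rnorm(25, 6, 0.3)),
                              rep(1, 50), rep(1:2, each = 25),
                              rep(c(1, 2, 3), c(50, 25, 25))),
               "DB")
})

test_that("overlapping unimodal fits and balanced bimodal fits give NC", {
  set.seed(53)
  # same location, different spread: no mean shift, NC
  nc1 <- classify_pattern(rnorm(50, 3, 0.3), rnorm(50, 3, 0.35), seed = 2)
  expect_equal(nc1, "NC")
  # identical bimodal structure with equal proportions: NC
  nc2 <- classify_pattern(c(rnorm(25, 1, 0.3), rnorm(25, 5, 0.3)),
                          c(rnorm(25, 1, 0.3), rnorm(25, 5, 0.3)), seed = 2)
  expect_equal(nc2, "NC")
})

test_that("component-count bound violations return NC", {
  set.seed(54)
  v <- make_test_view(rnorm(20, 2, 0.3), rnorm(20, 2, 0.3))
  # c1 = c2 = 1 but c_oa = 3 violates c1 + c2 >= c_oa
  z1 <- new_partition(rep(1, 20))
  z2 <- new_partition(rep(1, 20))
  zp <- new_partition(rep(1:3, c(14, 13, 13)))
  cs <- component_summary(v, z1, z2, zp)
  expect_equal(classify_dd_gene(cs, seed = 1), "NC")
})

test_that("equal-count components without matched overlap give DB", {
  set.seed(55)
  # both conditions bimodal but at shifted positions
  db <- classify_pattern(c(rnorm(25, 0, 0.3), rnorm(25, 4, 0.3)),
                         c(rnorm(25, 2, 0.3), rnorm(25, 8, 0.3)), seed = 3)
  expect_equal(db, "DB")
})

test_that("classification is deterministic given the seed", {
  set.seed(56)
  y1 <- rnorm(50, 2, 0.3)
  y2 <- c(rnorm(25, 2, 0.3), rnorm(25, 6, 0.3))
  expect_equal(classify_pattern(y1, y2, seed = 4),
               classify_pattern(y1, y2, seed = 4))
})
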