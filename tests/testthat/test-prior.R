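test_that("posterior updates follow the conjugate formulas", {
  pr <- ng_prior(m0 = 0.5, s0 = 0.2, a0 = 1.5, b0 = 2, alpha = 0.3)
  y <- c(1.2, -0.4, 2.1, 0.9)
  post <- ng_posterior_params(y, pr)
  n <- length(y)
  s_k <- pr$s0 + n
  m_k <- (pr$s0 * pr$m0 + sum(y)) / s_k
  expect_equal(post$s_k, s_k)
  expect_equal(post$m_k, m_k)
  expect_equal(post$a_k, pr$a0 + n)
  expect_equal(post$b_k, pr$b0 + sum(y^2) + pr$s0 * pr$m0^2 - s_k * m_k^2)
  expect_equal(post$n_k, n)
})

test_that("the posterior scale b_k equals twice the standard gamma rate", {
  # b_k / 2 must equal b0/2 + 0.5 * sum((y - ybar)^2) +
  #   0.5 * s0 * n * (ybar - m0)^2 / (s0 + n), the textbook posterior rate.
  pr <- ng_prior(m0 = -1, s0 = 0.7, a0 = 2, b0 = 3)
  y <- c(0.3, 1.7, -2.2, 0.5, 0.1)
  post <- ng_posterior_params(y, pr)
  n <- length(y)
  ybar <- mean(y)
  rate <- pr$b0 / 2 + 0.5 * sum((y - ybar)^2) +
    0.5 * pr$s0 * n * (ybar - pr$m0)^2 / (pr$s0 + n)
  expect_equal(post$b_k / 2, rate)
})

test_that("an empty component returns the prior and marginal zero", {
  pr <- ng_prior(m0 = 1, s0 = 0.5, a0 = 2, b0 = 1)
  post <- ng_posterior_params(numeric(), pr)
  expect_equal(post$m_k, pr$m0)
  expect_equal(post$s_k, pr$s0)
  expect_equal(post$a_k, pr$a0)
  expect_equal(post$b_k, pr$b0)
  expect_equal(log_component_marginal(post, pr), 0)
})

test_that("log_joint_predictive decomposes into its closed-form parts", {
  pr <- ng_prior()
  y <- c(0.4, 1.3, 0.8, 3.2, 3.4, 3.0)
  z <- new_partition(c(1, 1, 1, 2, 2, 2))
  expected <- 2 * log(pr$alpha) +
    lgamma(3) + log_component_marginal(ng_posterior_params(y[1:3], pr), pr) +
    lgamma(3) + log_component_marginal(ng_posterior_params(y[4:6], pr), pr)
  expect_equal(log_joint_predictive(y, z, pr), expected)
  expect_equal(log_joint_predictive(numeric(), new_partition(integer())), 0)
})

test_that("R and C++ log joint predictive agree", {
  pr <- ng_prior(m0 = 0.2, s0 = 0.05, a0 = 0.4, b0 = 0.7, alpha = 0.15)
  set.seed(11)
  y <- rnorm(30, 2, 1)
  labels <- rep(1:3, each = 10)
  expect_equal(
    log_joint_predictive(y, new_partition(labels), pr),
    ddseq:::.ljp_cpp(y, as.integer(labels), pr$m0, pr$s0, pr$a0, pr$b0,
                     pr$alpha),
    tolerance = 1e-12)
})

test_that("the Bayes factor score is symmetric and NA when untestable", {
  pr <- ng_prior()
  set.seed(3)
  y1 <- rnorm(20, 1)
  y2 <- rnorm(25, 4)
  z1 <- new_partition(rep(1, 20))
  z2 <- new_partition(rep(1, 25))
  zp <- new_partition(rep(1:2, c(20, 25)))
  zp_swap <- new_partition(rep(1:2, c(25, 20)))
  s12 <- bayes_factor_score(y1, y2, z1, z2, zp, pr)
  s21 <- bayes_factor_score(y2, y1, z2, z1, zp_swap, pr)
  expect_equal(s12, s21)
  expect_true(is.na(bayes_factor_score(numeric(), y2, NULL, z2, zp, pr)))
})

test_that("new_partition relabels gappy labels and tabulates sizes", {
  p <- new_partition(c(5, 5, 2, 2, 2, 9))
  expect_equal(p$K, 3L)
  # labels are compacted to 1..K preserving value order (2 < 5 < 9)
  expect_equal(p$labels, c(2L, 2L, 1L, 1L, 1L, 3L))
  expect_equal(p$sizes, c(3L, 2L, 1L))
})

test_that("posterior mean samples follow the scaled t distribution", {
  pr <- ng_prior(m0 = 0, s0 = 1, a0 = 4, b0 = 2)
  y <- c(2.0, 2.5, 1.5, 2.2, 1.8, 2.1, 2.4, 1.9)
  post <- ng_posterior_params(y, pr)
  d <- sample_component_mean_posterior(post, 200000, seed = 42)
  expect_equal(sample_component_mean_posterior(post, 5, seed = 42),
               sample_component_mean_posterior(post, 5, seed = 42))
  scale2 <- post$b_k / (post$a_k * post$s_k)
  expect_equal(mean(d), post$m_k, tolerance = 0.01)
  expect_equal(var(d), scale2 * post$a_k / (post$a_k - 2), tolerance = 0.05)
})
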