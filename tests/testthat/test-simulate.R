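test_that("nb_log_sd matches the lognormal moment identity", {
  expect_equal(nb_log_sd(50, 0.5), sqrt(log(1 + 1 / 50 + 0.5)))
  expect_equal(nb_log_sd(10, 2), sqrt(log(1 + 1 / 10 + 2)))
})

test_that("base parameter sampling respects the configured ranges", {
  spec <- sim_spec()
  base <- sample_base_params(500, spec, seed = 71)
  expect_true(all(base$mean >= exp(spec$log_mean_range[1]) &
                    base$mean <= exp(spec$log_mean_range[2])))
  expect_true(all(base$dispersion >= 0.1 & base$dispersion <= 2))
  expect_true(all(base$zero_prop >= 0 & base$zero_prop <= 0.6))
  expect_equal(base, sample_base_params(500, spec, seed = 71))
  # separation feasibility contract: even at delta_mu = 6 the low component
  # admits a negative binomial (variance comfortably above its mean), so
  # configured component separations are meaningful for every gene
  sigma <- nb_log_sd(base$mean, base$dispersion)
  var_lo <- (base$mean + base$dispersion * base$mean^2) * exp(-6 * sigma)
  mu_lo <- base$mean * exp(-3 * sigma)
  expect_true(all(var_lo >= 1.4 * mu_lo))
})

test_that("simulated datasets are reproducible and well-formed", {
  spec <- sim_spec(n_ee = 10, n_ep = 10, n_de = 5, n_dp = 5, n_dm = 5,
                   n_db = 5, cells_per_condition = 20, seed = 72)
  sim1 <- simulate_dd_data(spec)
  sim2 <- simulate_dd_data(spec)
  expect_identical(sim1$counts, sim2$counts)
  expect_equal(dim(sim1$counts), c(40L, 40L))
  expect_equal(sim1$condition, rep(1:2, each = 20))
  expect_equal(sim1$truth$gene, rownames(sim1$counts))
  expect_equal(as.vector(table(sim1$truth$category)[c("EE", "EP", "DE",
                                                      "DP", "DM", "DB")]),
               c(10L, 10L, 5L, 5L, 5L, 5L))
  expect_true(all(sim1$counts >= 0))
  expect_true(is.integer(sim1$counts))
})

test_that("component distances cycle over the grid for multimodal genes", {
  spec <- sim_spec(n_ee = 2, n_ep = 10, n_de = 2, n_dp = 10, n_dm = 10,
                   n_db = 10, cells_per_condition = 10, seed = 73)
  sim <- simulate_dd_data(spec)
  tr <- sim$truth
  for (cat in c("EP", "DP", "DM", "DB")) {
    expect_equal(tr$delta_mu[tr$category == cat],
                 rep_len(2:6, 10))
  }
  expect_true(all(is.na(tr$delta_mu[tr$category %in% c("EE", "DE")])))
})

test_that("DE shifts are drawn from the configured fold-change band", {
  spec <- sim_spec(n_ee = 0, n_ep = 0, n_de = 200, n_dp = 0, n_dm = 0,
                   n_db = 0, cells_per_condition = 2, seed = 74)
  sim <- simulate_dd_data(spec)
  fc <- sim$truth$log_fc
  expect_true(all(abs(fc) >= 2 * 0.42 & abs(fc) <= 3 * 0.42))
  expect_true(any(fc > 0) && any(fc < 0))
})

test_that("category-specific generative structure holds at scale", {
  base <- list(mean = 100, dispersion = 0.2, zero_prop = 0)
  spec <- sim_spec()
  sigma <- nb_log_sd(100, 0.2)

  dm <- simulate_gene("DM", base, delta_mu = 6, cells_per_condition = 4000,
                      spec = spec, seed = 75)
  # condition 1 sits at the low mode: its mean is well below condition 2's
  expect_lt(mean(dm$counts1), mean(dm$counts2))
  expect_equal(mean(log(dm$counts1[dm$counts1 > 0])),
               log(100) - 6 * sigma / 2, tolerance = 0.1)

  db <- simulate_gene("DB", base, delta_mu = 6, cells_per_condition = 4000,
                      spec = spec, seed = 76)
  # condition 1 unimodal at the centre; condition 2 bimodal around it
  expect_equal(mean(log(db$counts1[db$counts1 > 0])), log(100),
               tolerance = 0.1)
  lo2 <- log(100) - 6 * sigma / 2
  hi2 <- log(100) + 6 * sigma / 2
  l2 <- log(db$counts2[db$counts2 > 0])
  expect_equal(mean(l2 < log(100)), 0.5, tolerance = 0.05)
  expect_equal(mean(l2[l2 < log(100)]), lo2, tolerance = 0.15)
  expect_equal(mean(l2[l2 > log(100)]), hi2, tolerance = 0.15)
})

test_that("log-scale spread is constant across mixture components", {
  mu <- 100
  phi <- 0.3
  sigma <- nb_log_sd(mu, phi)
  base_var <- mu + phi * mu^2
  mus <- mu * exp(c(-1, 1) * 6 * sigma / 2)
  vars <- base_var * exp(c(-1, 1) * 6 * sigma)
  set.seed(78)
  lo <- ddseq:::.rnb_component(50000, mus[1], vars[1])
  hi <- ddseq:::.rnb_component(50000, mus[2], vars[2])
  sd_lo <- sd(log(lo[lo > 0]))
  sd_hi <- sd(log(hi[hi > 0]))
  # components share their CV by construction, so they have equal log-scale
  # spread (the raw value exceeds the lognormal moment identity sigma because
  # the negative binomial is right-skewed)
  expect_equal(sd_lo / sd_hi, 1, tolerance = 0.1)
  expect_gt(sd_lo, 0.8 * sigma)
  expect_lt(sd_lo, 1.5 * sigma)
})

test_that("zeroes are injected at the same rate in both conditions", {
  base <- list(mean = 200, dispersion = 0.1, zero_prop = 0.4)
  g <- simulate_gene("EE", base, cells_per_condition = 5000,
                     spec = sim_spec(), seed = 77)
  expect_equal(mean(g$counts1 == 0), 0.4, tolerance = 0.03)
  expect_equal(mean(g$counts2 == 0), 0.4, tolerance = 0.03)
})

test_that("invalid categories are rejected", {
  expect_error(simulate_gene("XX", list(mean = 10, dispersion = 1,
                                        zero_prop = 0)),
               "invalid simulation category")
})
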