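#' Specification of a simulated two-condition experiment
#'
#' Describes the negative-binomial (mixture) simulation used for power and
#' classification benchmarking. Genes fall into six categories: the nulls
#' EE (one component, identical in both conditions) and EP (two components
#' with equal proportions in both conditions), and the differential
#' categories DE (one component per condition, shifted mean), DP (shared
#' component locations, low-mode proportion `dp_props[1]` in condition 1
#' versus `dp_props[2]` in condition 2), DM (unimodal condition 1 matching
#' the lower mode of a bimodal condition 2), and DB (unimodal condition 1
#' centred half-way, on the log scale, between the two condition-2 modes).
#' Multimodal categories place their component log-means `delta_mu * sigma`
#' apart, where `sigma` is the within-component log-scale standard
#' deviation implied by the gene's negative-binomial parameters; `sigma`
#' is constant across components (component raw-scale standard deviations
#' scale by the same fold-change as the means), and `delta_mu` cycles over
#' `delta_mu_grid`. Zeroes are injected at a gene-specific rate that does
#' not vary by condition.
#'
#' @param cells_per_condition Cells in each condition (default 50).
#' @param n_ee,n_ep,n_de,n_dp,n_dm,n_db Genes per category (defaults 4000,
#'   4000, 500, 500, 500, 500 for the full-size study).
#' @param delta_mu_grid Component mean distances (default 2:6, equally
#'   represented).
#' @param log_mean_loc,log_mean_scale Location and scale of the normal
#'   distribution of log base means (defaults `log(50)` and 1.5).
#' @param log_mean_range Truncation range for log base means. The lower
#'   default `log(33)` is the smallest base mean at which the low
#'   component of a `delta_mu = 6` separation still admits a
#'   negative-binomial with the required variance (`var >= 1.5 * mean`)
#'   across the whole dispersion range, keeping component separations
#'   meaningful for every simulated gene.
#' @param dispersion_range Range of the log-uniform NB dispersion `phi`
#'   (variance = mu + phi * mu^2).
#' @param zero_prop_range Range of the uniform zero proportion.
#' @param fc_sd Scale of DE log fold-changes: shifts are drawn uniformly
#'   from `[2, 3] * fc_sd` (natural-log units) with random sign; the
#'   default 0.42 puts the median absolute log2 fold-change near 1.5.
#' @param dp_props Low-mode proportions for DP genes in conditions 1 and 2.
#' @param ep_low_prop Low-mode proportion of the EP null (both conditions).
#' @param seed Integer seed.
#'
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(cells_per_condition = 50,
                     n_ee = 4000, n_ep = 4000,
                     n_de = 500, n_dp = 500, n_dm = 500, n_db = 500,
                     delta_mu_grid = 2:6,
                     log_mean_loc = log(50), log_mean_scale = 1.5,
                     log_mean_range = log(c(33, 1000)),
                     dispersion_range = c(0.1, 2),
                     zero_prop_range = c(0, 0.6),
                     fc_sd = 0.42,
                     dp_props = c(0.33, 0.66),
                     ep_low_prop = 0.5,
                     seed = 1L) {
  stopifnot(cells_per_condition >= 2, all(delta_mu_grid > 0),
            fc_sd > 0, length(dp_props) == 2, all(dp_props > 0 & dp_props < 1))
  structure(list(cells_per_condition = as.integer(cells_per_condition),
                 n_per_category = c(EE = n_ee, EP = n_ep, DE = n_de,
                                    DP = n_dp, DM = n_dm, DB = n_db),
                 delta_mu_grid = delta_mu_grid,
                 log_mean_loc = log_mean_loc,
                 log_mean_scale = log_mean_scale,
                 log_mean_range = log_mean_range,
                 dispersion_range = dispersion_range,
                 zero_prop_range = zero_prop_range,
                 fc_sd = fc_sd, dp_props = dp_props,
                 ep_low_prop = ep_low_prop,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

#' @export
print.sim_spec <- function(x, ...) {
  cat("<sim_spec>", sum(x$n_per_category), "genes,",
      x$cells_per_condition, "cells/condition; per category:",
      paste(names(x$n_per_category), x$n_per_category, sep = "=",
            collapse = " "), "\n")
  invisible(x)
}

#' Log-scale within-component standard deviation of an NB gene
#'
#' Standard deviation of the lognormal distribution matching a negative
#' binomial with mean `mu` and dispersion `phi`
#' (variance `mu + phi * mu^2`): `sqrt(log(1 + 1/mu + phi))`.
#'
#' @param mu NB mean.
#' @param phi NB dispersion.
#' @return Log-scale standard deviation.
#' @export
nb_log_sd <- function(mu, phi) sqrt(log(1 + 1 / mu + phi))

#' Sample base negative-binomial parameters
#'
#' Draws gene-level base parameters mimicking scRNA-seq expression: the
#' log base mean is normal (truncated to `log_mean_range`), the dispersion
#' is log-uniform, and the zero proportion uniform; the zero proportion is
#' never varied by condition.
#'
#' @param n Number of genes.
#' @param spec A [sim_spec()] (only the sampler fields are used).
#' @param seed Optional integer seed.
#'
#' @return Tibble with columns `mean`, `dispersion`, `zero_prop`.
#' @export
sample_base_params <- function(n, spec = sim_spec(), seed = NULL) {
  if (!is.null(seed)) {
    old <- .save_rng_state()
    on.exit(.restore_rng_state(old))
    set.seed(seed)
  }
  lm <- rnorm(n, spec$log_mean_loc, spec$log_mean_scale)
  lm <- pmin(pmax(lm, spec$log_mean_range[1]), spec$log_mean_range[2])
  phi <- exp(runif(n, log(spec$dispersion_range[1]),
                   log(spec$dispersion_range[2])))
  zp <- runif(n, spec$zero_prop_range[1], spec$zero_prop_range[2])
  tibble::tibble(mean = exp(lm), dispersion = phi, zero_prop = zp)
}

# NB draws for one component with a prescribed mean and variance; the size
# parameter follows from var = mu + mu^2 / size (clamped near the Poisson
# boundary for numerical safety)
.rnb_component <- function(n, mu, var) {
  size <- mu^2 / max(var - mu, mu^2 / 1e6)
  rnbinom(n, mu = mu, size = size)
}

# Mixture with component means `mus` and variances `vars`: the raw-scale
# standard deviation of each component scales with its mean, keeping the
# log-scale spread constant across components.
.rnb_mix <- function(n, mus, vars, props) {
  comp <- sample.int(length(mus), n, replace = TRUE, prob = props)
  out <- integer(n)
  for (k in seq_along(mus)) {
    idx <- comp == k
    if (any(idx)) out[idx] <- .rnb_component(sum(idx), mus[k], vars[k])
  }
  out
}

#' Simulate one gene
#'
#' Generates negative-binomial counts for both conditions under one of the
#' six generative categories, with zeroes injected at the gene's zero
#' proportion identically in both conditions. For multimodal categories the
#' two component means sit at `mu * exp(-delta_mu * sigma / 2)` and
#' `mu * exp(+delta_mu * sigma / 2)` where `sigma = nb_log_sd(mu, phi)`, so
#' the log-scale separation is `delta_mu` within-component standard
#' deviations. Component variances scale with the squared fold-change
#' (coefficient of variation preserved), so `sigma` is the log-scale
#' standard deviation of *every* component, not just the base one; DE
#' shifts likewise scale mean and standard deviation together (a pure
#' log-scale location shift).
#'
#' @param category One of `"EE"`, `"EP"`, `"DE"`, `"DP"`, `"DM"`, `"DB"`.
#' @param base One-row tibble/list with `mean`, `dispersion`, `zero_prop`.
#' @param delta_mu Component mean distance (ignored for EE and DE).
#' @param cells_per_condition Cells per condition.
#' @param spec A [sim_spec()] providing proportions and fold-change scale.
#' @param seed Optional integer seed.
#'
#' @return List with `counts1`, `counts2` (integer vectors) and `truth`
#'   (one-row tibble of generating parameters).
#' @export
simulate_gene <- function(category, base, delta_mu = NA,
                          cells_per_condition = 50, spec = sim_spec(),
                          seed = NULL) {
  if (!category %in% c("EE", "EP", "DE", "DP", "DM", "DB")) {
    stop("invalid simulation category: ", category, call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- .save_rng_state()
    on.exit(.restore_rng_state(old))
    set.seed(seed)
  }
  n <- cells_per_condition
  mu <- base$mean
  phi <- base$dispersion
  sigma <- nb_log_sd(mu, phi)
  base_var <- mu + phi * mu^2
  # component means delta_mu * sigma apart on the log scale; variances
  # scale with the squared fold-change so sigma is common to components
  mus <- mu * exp(c(-1, 1) * delta_mu * sigma / 2)
  vars <- base_var * exp(c(-1, 1) * delta_mu * sigma)
  fc <- NA_real_
  if (category == "EE") {
    y1 <- rnbinom(n, mu = mu, size = 1 / phi)
    y2 <- rnbinom(n, mu = mu, size = 1 / phi)
  } else if (category == "EP") {
    pr <- c(spec$ep_low_prop, 1 - spec$ep_low_prop)
    y1 <- .rnb_mix(n, mus, vars, pr)
    y2 <- .rnb_mix(n, mus, vars, pr)
  } else if (category == "DE") {
    fc <- sample(c(-1, 1), 1) * runif(1, 2 * spec$fc_sd, 3 * spec$fc_sd)
    y1 <- rnbinom(n, mu = mu, size = 1 / phi)
    y2 <- .rnb_component(n, mu * exp(fc), base_var * exp(2 * fc))
  } else if (category == "DP") {
    y1 <- .rnb_mix(n, mus, vars, c(spec$dp_props[1], 1 - spec$dp_props[1]))
    y2 <- .rnb_mix(n, mus, vars, c(spec$dp_props[2], 1 - spec$dp_props[2]))
  } else if (category == "DM") {
    y1 <- .rnb_component(n, mus[1], vars[1])
    y2 <- .rnb_mix(n, mus, vars, c(0.5, 0.5))
  } else {  # DB: condition-1 mean half-way between the condition-2 modes
    y1 <- rnbinom(n, mu = mu, size = 1 / phi)
    y2 <- .rnb_mix(n, mus, vars, c(0.5, 0.5))
  }
  drop1 <- rbinom(n, 1, base$zero_prop) == 1
  drop2 <- rbinom(n, 1, base$zero_prop) == 1
  y1[drop1] <- 0L
  y2[drop2] <- 0L
  list(counts1 = as.integer(y1), counts2 = as.integer(y2),
       truth = tibble::tibble(category = category, base_mean = mu,
                              dispersion = phi, zero_prop = base$zero_prop,
                              sigma_log = sigma, delta_mu = delta_mu,
                              log_fc = fc))
}

#' Simulate a full two-condition dataset
#'
#' Generates the complete benchmark dataset described by a [sim_spec()]:
#' counts for all genes, per-cell condition labels, and the ground-truth
#' table used by [evaluate_run()].
#'
#' @param spec A [sim_spec()].
#'
#' @return List with `counts` (genes x cells integer matrix), `condition`
#'   (integer vector, 1/2), and `truth` (tibble keyed by `gene`).
#' @export
simulate_dd_data <- function(spec = sim_spec()) {
  stopifnot(inherits(spec, "sim_spec"))
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  set.seed(spec$seed)
  cats <- rep(names(spec$n_per_category), spec$n_per_category)
  n_genes <- length(cats)
  base <- sample_base_params(n_genes, spec)
  deltas <- rep(NA_real_, n_genes)
  needs_delta <- cats %in% c("EP", "DP", "DM", "DB")
  for (cat in c("EP", "DP", "DM", "DB")) {
    idx <- which(cats == cat)
    deltas[idx] <- rep_len(spec$delta_mu_grid, length(idx))
  }
  n <- spec$cells_per_condition
  counts <- matrix(0L, n_genes, 2L * n)
  truth <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    sim <- simulate_gene(cats[g], base[g, ], deltas[g], n, spec)
    counts[g, ] <- c(sim$counts1, sim$counts2)
    truth[[g]] <- sim$truth
  }
  rownames(counts) <- sprintf("gene%05d", seq_len(n_genes))
  colnames(counts) <- c(sprintf("c1_%04d", seq_len(n)),
                        sprintf("c2_%04d", seq_len(n)))
  truth <- dplyr::bind_rows(truth)
  truth$gene <- rownames(counts)
  truth <- dplyr::relocate(truth, "gene")
  list(counts = counts,
       condition = rep(1:2, each = n),
       truth = truth)
}
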