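.prior_args <- function(prior) {
  list(prior$m0, prior$s0, prior$a0, prior$b0, prior$alpha)
}

.score_gene <- function(nonzero_log, cond_nz, prior, opts) {
  bt <- .bi_table(opts)
  do.call(.score_gene_cpp,
          c(list(as.numeric(nonzero_log), as.integer(cond_nz),
                 opts$k_max, opts$min_component_size,
                 opts$merge_variance_ratio, opts$split_variance_ratio,
                 bt$n, bt$cut),
            .prior_args(prior)))
}

#' Permutation test of the Bayes factor score for one gene
#'
#' Computes the observed score from partition estimates fitted within each
#' condition and pooled, then compares it to a permutation null. Without a
#' covariate, condition labels are shuffled over all cells (each cell keeps
#' its zero/nonzero status, so condition sizes are preserved and the number
#' of nonzero cells per condition varies across permutations); the pooled
#' partition ignores labels and is fitted once. With a covariate, residual
#' permutation is used instead: a linear model of the nonzero log values on
#' the covariate is fitted, residuals are shuffled and added back to the
#' fitted values, and all three partitions are re-estimated. The empirical
#' p-value uses the add-one estimator `(1 + #{perm >= obs}) / (1 + n_perm)`
#' and is therefore never zero.
#'
#' @param gene A gene view from [make_gene_views()] (fields `nonzero_log`,
#'   `zero_flag`, `condition`, optional `covariate`).
#' @param n_perm Number of permutations (the package default pipeline uses
#'   1000).
#' @param prior An [ng_prior()].
#' @param opts A [partition_options()].
#' @param seed Optional integer seed.
#'
#' @return A list with `score`, `p_perm`, `perm_scores`, `testable`, and
#'   the three fitted partitions (`z1`, `z2`, `z_pooled`) on the nonzero
#'   values.
#' @export
permutation_test <- function(gene, n_perm = 1000, prior = ng_prior(),
                             opts = partition_options(), seed = NULL) {
  stopifnot(inherits(prior, "ng_prior"), inherits(opts, "partition_options"),
            n_perm >= 1)
  if (!is.null(seed)) {
    old <- .save_rng_state()
    on.exit(.restore_rng_state(old))
    set.seed(seed)
  }
  cond <- gene$condition
  nz <- !gene$zero_flag
  y <- gene$nonzero_log
  cond_nz <- cond[nz]
  n_nz <- tabulate(cond_nz, nbins = 2L)
  if (any(n_nz < opts$min_component_size)) {
    return(list(score = NA_real_, p_perm = NA_real_, perm_scores = numeric(),
                testable = FALSE, z1 = NULL, z2 = NULL, z_pooled = NULL))
  }
  obs <- .score_gene(y, cond_nz, prior, opts)
  bt <- .bi_table(opts)
  if (is.null(gene$covariate)) {
    y_all <- numeric(length(cond))
    y_all[nz] <- y
    pooled_ljp <- .ljp_cpp(y, obs$labels_pooled, prior$m0, prior$s0,
                           prior$a0, prior$b0, prior$alpha)
    perm <- do.call(.perm_scores_cpp,
                    c(list(y_all, nz, as.integer(cond), as.integer(n_perm),
                           pooled_ljp, opts$k_max, opts$min_component_size,
                           opts$merge_variance_ratio,
                           opts$split_variance_ratio, bt$n, bt$cut),
                      .prior_args(prior)))
  } else {
    covar <- gene$covariate[nz]
    if (stats::var(covar) <= 0) {
      warning("constant covariate; falling back to plain permutation",
              call. = FALSE)
      y_all <- numeric(length(cond))
      y_all[nz] <- y
      pooled_ljp <- .ljp_cpp(y, obs$labels_pooled, prior$m0, prior$s0,
                             prior$a0, prior$b0, prior$alpha)
      perm <- do.call(.perm_scores_cpp,
                      c(list(y_all, nz, as.integer(cond), as.integer(n_perm),
                             pooled_ljp, opts$k_max, opts$min_component_size,
                             opts$merge_variance_ratio,
                             opts$split_variance_ratio, bt$n, bt$cut),
                        .prior_args(prior)))
    } else {
      fit <- lm(y ~ covar)
      perm <- do.call(.perm_scores_resid_cpp,
                      c(list(as.numeric(fitted(fit)),
                             as.numeric(residuals(fit)),
                             as.integer(cond_nz), as.integer(n_perm),
                             opts$k_max, opts$min_component_size,
                             opts$merge_variance_ratio,
                             opts$split_variance_ratio, bt$n, bt$cut),
                        .prior_args(prior)))
    }
  }
  list(score = obs$score,
       p_perm = (1 + sum(perm >= obs$score)) / (1 + n_perm),
       perm_scores = perm,
       testable = TRUE,
       z1 = new_partition(obs$labels1),
       z2 = new_partition(obs$labels2),
       z_pooled = new_partition(obs$labels_pooled))
}

#' Residual-permutation of covariate-adjusted values
#'
#' Fits a linear model of the nonzero log values on the covariate (pooled
#' over conditions), permutes the residuals, and returns fitted values plus
#' permuted residuals. This preserves the covariate-expression relationship
#' while breaking any association with condition. With a constant covariate
#' the values themselves are permuted, with a warning.
#'
#' @param gene A gene view with a `covariate` field.
#' @param seed Optional integer seed.
#'
#' @return Numeric vector of permuted nonzero log values (same length and
#'   order as `gene$nonzero_log`).
#' @export
residual_permutation_values <- function(gene, seed = NULL) {
  if (!is.null(seed)) {
    old <- .save_rng_state()
    on.exit(.restore_rng_state(old))
    set.seed(seed)
  }
  y <- gene$nonzero_log
  covar <- gene$covariate[!gene$zero_flag]
  if (is.null(covar)) stop("gene view has no covariate", call. = FALSE)
  if (stats::var(covar) <= 0) {
    warning("constant covariate; falling back to plain permutation",
            call. = FALSE)
    return(y[sample.int(length(y))])
  }
  fit <- lm(y ~ covar)
  as.numeric(fitted(fit)) + as.numeric(residuals(fit))[sample.int(length(y))]
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment (wraps
#' `stats::p.adjust(method = "BH")`, which enforces monotonicity).
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#'
#' @return Vector of adjusted q-values.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric())
  p.adjust(p_values, method = "BH")
}

#' Mean-shift rescue of non-significant genes
#'
#' The Bayes factor score depends on the estimated partition; to stay
#' robust to partition misspecification, genes that failed the permutation
#' test are additionally screened for an overall mean shift of the nonzero
#' log values with a two-sample (Welch) t-statistic, BH-adjusted over the
#' rescue set.
#'
#' @param genes Named list of gene views that were not significant.
#' @param fdr_target FDR threshold for the rescue set (default 0.05).
#'
#' @return Tibble with columns `gene`, `t_p`, `t_q`, `rescued`.
#' @export
mean_shift_rescue <- function(genes, fdr_target = 0.05) {
  if (length(genes) == 0) {
    return(tibble::tibble(gene = character(), t_p = numeric(),
                          t_q = numeric(), rescued = logical()))
  }
  p <- vapply(genes, function(g) {
    y <- g$nonzero_log
    cnd <- g$condition[!g$zero_flag]
    n <- tabulate(cnd, nbins = 2L)
    if (any(n < 2)) return(NA_real_)
    if (stats::var(y[cnd == 1]) + stats::var(y[cnd == 2]) <= 0) {
      return(if (mean(y[cnd == 1]) == mean(y[cnd == 2])) 1 else 0)
    }
    t.test(y[cnd == 1], y[cnd == 2])$p.value
  }, numeric(1))
  q <- rep(NA_real_, length(p))
  q[!is.na(p)] <- bh_adjust(p[!is.na(p)])
  tibble::tibble(gene = names(genes), t_p = p, t_q = q,
                 rescued = !is.na(q) & q <= fdr_target)
}

#' Fisher exact rescue for differential proportion
#'
#' The Bayes factor score is small when the within-condition clusterings
#' agree with the pooled clustering, as in a pure differential-proportion
#' pattern. For a gene that is not significant by permutation but has the
#' same number of components within each condition as overall, the
#' condition x pooled-component contingency table over nonzero cells is
#' tested for independence with Fisher's exact test; `TRUE` (classify as
#' DP) when p < 0.05.
#'
#' @param gene A gene view.
#' @param z1,z2,z_pooled Partitions from the observed fit.
#' @param min_size Minimum component size counted (default 3).
#' @param p_cutoff Significance cutoff (default 0.05).
#'
#' @return Logical.
#' @export
fisher_dp_rescue <- function(gene, z1, z2, z_pooled, min_size = 3,
                             p_cutoff = 0.05) {
  c1 <- effective_component_count(z1, min_size)
  c2 <- effective_component_count(z2, min_size)
  c_oa <- effective_component_count(z_pooled, min_size)
  if (c_oa < 2 || c1 != c_oa || c2 != c_oa) return(FALSE)
  cond_nz <- gene$condition[!gene$zero_flag]
  tab <- table(factor(cond_nz, levels = 1:2), z_pooled$labels)
  if (ncol(tab) < 2) return(FALSE)
  fisher.test(tab)$p.value < p_cutoff
}
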