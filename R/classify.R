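#' Component summary of a significant gene
#'
#' Gathers, for each condition and for the pooled fit, the normal-gamma
#' posteriors and cell counts of every component with at least `min_size`
#' cells (smaller components are treated as outliers and not counted).
#' Components are ordered by posterior mean.
#'
#' @param gene A gene view from [make_gene_views()].
#' @param z1,z2,z_pooled Partitions of the condition-1, condition-2, and
#'   pooled nonzero values.
#' @param prior An [ng_prior()].
#' @param min_size Minimum cells per counted component (default 3).
#'
#' @return An object of class `component_summary` with per-side lists of
#'   posteriors, sizes, and within-condition proportions, plus the counts
#'   `c1`, `c2`, `c_oa`.
#' @export
component_summary <- function(gene, z1, z2, z_pooled, prior = ng_prior(),
                              min_size = 3) {
  cond_nz <- gene$condition[!gene$zero_flag]
  y <- gene$nonzero_log
  side <- function(values, part) {
    keep <- which(part$sizes >= min_size)
    posts <- lapply(keep, function(k) {
      ng_posterior_params(values[part$labels == k], prior)
    })
    m <- vapply(posts, function(p) p$m_k, numeric(1))
    ord <- order(m)
    list(posts = posts[ord], sizes = part$sizes[keep][ord],
         means = m[ord],
         proportions = if (length(keep)) part$sizes[keep][ord] /
           sum(part$sizes[keep]) else numeric())
  }
  structure(list(cond1 = side(y[cond_nz == 1], z1),
                 cond2 = side(y[cond_nz == 2], z2),
                 pooled = side(y, z_pooled),
                 c1 = sum(z1$sizes >= min_size),
                 c2 = sum(z2$sizes >= min_size),
                 c_oa = sum(z_pooled$sizes >= min_size)),
            class = "component_summary")
}

#' Posterior overlap of two component means
#'
#' Draws `n_draws` independent samples from each component's Student-t mean
#' posterior; the components overlap when the 100% credible interval of the
#' sampled differences contains zero (i.e. the differences change sign).
#'
#' @param post_i,post_j [ng_posterior_params()] objects for the two
#'   components.
#' @param n_draws Draws per component (default 10000).
#' @param seed Optional integer seed.
#'
#' @return Logical: do the posterior means overlap?
#' @export
component_overlap <- function(post_i, post_j, n_draws = 10000, seed = NULL) {
  if (!is.null(seed)) {
    old <- .save_rng_state()
    on.exit(.restore_rng_state(old))
    set.seed(seed)
  }
  di <- sample_component_mean_posterior(post_i, n_draws)
  dj <- sample_component_mean_posterior(post_j, n_draws)
  d <- di - dj
  min(d) <= 0 && max(d) >= 0
}

.overlap_matrix <- function(posts1, posts2, n_draws) {
  draws1 <- lapply(posts1, sample_component_mean_posterior, n_draws = n_draws)
  draws2 <- lapply(posts2, sample_component_mean_posterior, n_draws = n_draws)
  out <- matrix(FALSE, length(posts1), length(posts2))
  for (i in seq_along(posts1)) {
    for (j in seq_along(posts2)) {
      d <- draws1[[i]] - draws2[[j]]
      out[i, j] <- min(d) <= 0 && max(d) >= 0
    }
  }
  out
}

#' Classify a significant differentially distributed gene
#'
#' Assigns one of the categories DE, DP, DM, DB, or NC from the component
#' structure of a gene already called significant. Writing `c1`, `c2` and
#' `c_oa` for the number of counted components in condition 1, condition 2
#' and overall, an interpretable gene must satisfy
#' `c1 + c2 >= c_oa >= min(c1, c2)`; anything outside these bounds is NC.
#' The rules, matching the four canonical generative patterns:
#'
#' * `c1 = c2 = 1`: DE when the two single components' mean posteriors do
#'   not overlap; NC when they do (a variance-only difference).
#' * `c1 = c2 = K >= 2` and every mean-rank-matched cross-condition pair
#'   overlaps: DP when the component proportions differ (exact test on the
#'   2 x K table at 0.05), otherwise NC.
#' * `c1 = c2 = K >= 2` without a fully overlapping matching: DB (modes
#'   shared in number but shifted).
#' * `c1 != c2`: DM when every component of the condition with fewer modes
#'   overlaps some component of the other condition; DB when at least one
#'   overlaps none.
#'
#' @param summary A [component_summary()].
#' @param n_draws Posterior draws per component for overlap assessment
#'   (default 10000).
#' @param seed Optional integer seed (classification is deterministic given
#'   the seed).
#' @param prop_cutoff Significance cutoff for the proportion test in the
#'   DP rule (default 0.05).
#'
#' @return A single character category in
#'   `c("DE", "DP", "DM", "DB", "NC")`.
#' @export
classify_dd_gene <- function(summary, n_draws = 10000, seed = NULL,
                             prop_cutoff = 0.05) {
  stopifnot(inherits(summary, "component_summary"))
  if (!is.null(seed)) {
    old <- .save_rng_state()
    on.exit(.restore_rng_state(old))
    set.seed(seed)
  }
  c1 <- summary$c1
  c2 <- summary$c2
  c_oa <- summary$c_oa
  if (c1 == 0 || c2 == 0) return("NC")
  if (!(c1 + c2 >= c_oa && c_oa >= min(c1, c2))) return("NC")
  ov <- .overlap_matrix(summary$cond1$posts, summary$cond2$posts, n_draws)
  if (c1 == 1 && c2 == 1) {
    return(if (ov[1, 1]) "NC" else "DE")
  }
  if (c1 == c2) {
    matched <- all(diag(ov))  # components are mean-ordered on both sides
    if (!matched) return("DB")
    tab <- rbind(summary$cond1$sizes, summary$cond2$sizes)
    p <- fisher.test(tab)$p.value
    return(if (p < prop_cutoff) "DP" else "NC")
  }
  if (c1 < c2) {
    small_covered <- all(apply(ov, 1, any))
  } else {
    small_covered <- all(apply(ov, 2, any))
  }
  if (small_covered) "DM" else "DB"
}
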