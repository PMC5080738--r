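#' Conjugate normal-gamma prior for the product partition mixture
#'
#' The log-transformed nonzero expression values of a gene are modelled,
#' conditional on a partition of cells into components, as independent
#' normals whose mean/precision pair carries a conjugate normal-gamma prior
#' `NG(m0, s0, a0/2, 2/b0)`: the precision `tau` has a gamma distribution
#' with shape `a0/2` and rate `b0/2`, and given `tau` the mean is normal
#' with mean `m0` and precision `s0 * tau`. `alpha` is the Dirichlet
#' concentration governing the partition prior. The defaults encode a
#' heavy-tailed, weakly informative prior on log-expression.
#'
#' @param m0 Prior mean (log-expression units).
#' @param s0 Prior precision scaling (> 0).
#' @param a0 Gamma shape numerator (> 0).
#' @param b0 Gamma scale denominator (> 0).
#' @param alpha Dirichlet concentration (> 0).
#'
#' @return An object of class `ng_prior`.
#' @export
#' @examples
#' ng_prior()
ng_prior <- function(m0 = 0, s0 = 0.01, a0 = 0.01, b0 = 0.01, alpha = 0.01) {
  stopifnot(is.finite(m0), s0 > 0, a0 > 0, b0 > 0, alpha > 0)
  structure(list(m0 = m0, s0 = s0, a0 = a0, b0 = b0, alpha = alpha),
            class = "ng_prior")
}

#' @export
print.ng_prior <- function(x, ...) {
  cat(sprintf(
    "<ng_prior> m0 = %g, s0 = %g, a0 = %g, b0 = %g, alpha = %g\n",
    x$m0, x$s0, x$a0, x$b0, x$alpha))
  invisible(x)
}

#' Posterior normal-gamma parameters for one component
#'
#' Conjugate update of the normal-gamma prior given the log-expression
#' values assigned to a single mixture component:
#' `s_k = s0 + n`, `m_k = (s0 m0 + sum(y)) / s_k`, `a_k = a0 + n`,
#' `b_k = b0 + sum(y^2) + s0 m0^2 - s_k m_k^2`. An empty component returns
#' the prior itself.
#'
#' @param values Numeric vector of log-expression values in the component.
#' @param prior An [ng_prior()].
#'
#' @return An object of class `ng_posterior` with fields `m_k`, `s_k`,
#'   `a_k`, `b_k`, `n_k`.
#' @export
#' @examples
#' ng_posterior_params(c(1, 1), ng_prior())
ng_posterior_params <- function(values, prior = ng_prior()) {
  stopifnot(inherits(prior, "ng_prior"))
  if (length(values) && !all(is.finite(values))) {
    stop("`values` must be finite log-expression measurements", call. = FALSE)
  }
  n <- length(values)
  s_k <- prior$s0 + n
  m_k <- (prior$s0 * prior$m0 + sum(values)) / s_k
  a_k <- prior$a0 + n
  b_k <- prior$b0 + sum(values^2) + prior$s0 * prior$m0^2 - s_k * m_k^2
  structure(list(m_k = m_k, s_k = s_k, a_k = a_k, b_k = b_k, n_k = n),
            class = "ng_posterior")
}

#' Log marginal likelihood of one component
#'
#' Closed-form log marginal density of the values in a component after
#' integrating the normal mean and precision against the normal-gamma
#' prior. The component-specific part is
#' `lgamma(a_k/2) - (a_k/2) log(b_k/2) - log(s_k)/2`; the full normalising
#' constant `(2*pi)^(-n/2) (b0/2)^(a0/2) s0^(1/2) / gamma(a0/2)` is included
#' so the value is an exact log marginal likelihood (it cancels between
#' numerator and denominator of the Bayes factor score apart from prior
#' terms, but makes the closed form checkable against numerical
#' integration).
#'
#' @param post An [ng_posterior_params()] object.
#' @param prior The [ng_prior()] used for the update.
#'
#' @return A single numeric log marginal likelihood.
#' @export
log_component_marginal <- function(post, prior = ng_prior()) {
  stopifnot(inherits(post, "ng_posterior"), inherits(prior, "ng_prior"))
  if (post$b_k <= 0) {
    stop("posterior scale `b_k` must be positive (corrupt input?)",
         call. = FALSE)
  }
  lgamma(post$a_k / 2) - (post$a_k / 2) * log(post$b_k / 2) -
    0.5 * log(post$s_k) -
    (post$n_k / 2) * log(2 * pi) + (prior$a0 / 2) * log(prior$b0 / 2) +
    0.5 * log(prior$s0) - lgamma(prior$a0 / 2)
}

#' Construct a partition of cells into components
#'
#' @param labels Integer vector of per-cell component indices; every
#'   component between 1 and `max(labels)` must be non-empty.
#'
#' @return An object of class `dd_partition` with fields `labels`, `K`
#'   (number of components) and `sizes` (cells per component).
#' @export
#' @examples
#' new_partition(c(1, 1, 2, 2, 2))
new_partition <- function(labels) {
  labels <- as.integer(labels)
  if (length(labels) == 0) {
    return(structure(list(labels = integer(), K = 0L, sizes = integer()),
                     class = "dd_partition"))
  }
  u <- sort(unique(labels))
  if (!identical(u, seq_along(u))) {
    labels <- match(labels, u)  # relabel to 1..K, dropping gaps
  }
  sizes <- tabulate(labels)
  structure(list(labels = labels, K = length(sizes), sizes = sizes),
            class = "dd_partition")
}

#' @export
print.dd_partition <- function(x, ...) {
  cat(sprintf("<dd_partition> K = %d, sizes = %s\n", x$K,
              paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Log joint predictive of data and partition
#'
#' The closed-form log of `alpha^K * prod_k Gamma(n_k) * f(y^(k))`, the
#' joint predictive density of the observed values and a partition under
#' the conjugate product partition model, using the same normalising
#' constant convention as [log_component_marginal()]. This is the quantity
#' maximised by the MAP partition and differenced in the Bayes factor
#' score.
#'
#' @param values Numeric vector of log-expression values.
#' @param partition A [new_partition()] covering `values`.
#' @param prior An [ng_prior()].
#'
#' @return A single numeric value.
#' @export
log_joint_predictive <- function(values, partition, prior = ng_prior()) {
  stopifnot(inherits(prior, "ng_prior"))
  if (inherits(partition, "dd_partition")) {
    labels <- partition$labels
  } else {
    labels <- new_partition(partition)$labels
  }
  if (length(values) != length(labels)) {
    stop("`values` and partition labels have different lengths",
         call. = FALSE)
  }
  if (length(values) == 0) return(0)
  K <- max(labels)
  total <- K * log(prior$alpha)
  for (k in seq_len(K)) {
    yk <- values[labels == k]
    post <- ng_posterior_params(yk, prior)
    total <- total + lgamma(length(yk)) + log_component_marginal(post, prior)
  }
  total
}

#' Bayes factor score for differential distribution
#'
#' Approximate log Bayes factor comparing two independent
#' condition-specific product partition models against one pooled model,
#' evaluated at the supplied partition estimates:
#' `score = LJP(y1, z1) + LJP(y2, z2) - LJP(pooled, z_pooled)` where `LJP`
#' is [log_joint_predictive()]. High values are evidence that the gene is
#' differentially distributed; significance is assessed by permutation.
#'
#' @param values1,values2 Nonzero log-expression values in condition 1 and 2.
#' @param z1,z2,z_pooled Partitions fitted to condition 1, condition 2, and
#'   the pooled values (`c(values1, values2)`).
#' @param prior An [ng_prior()].
#'
#' @return A single numeric score, or `NA` if either condition has no
#'   nonzero values (untestable gene).
#' @export
bayes_factor_score <- function(values1, values2, z1, z2, z_pooled,
                               prior = ng_prior()) {
  if (length(values1) == 0 || length(values2) == 0) return(NA_real_)
  log_joint_predictive(values1, z1, prior) +
    log_joint_predictive(values2, z2, prior) -
    log_joint_predictive(c(values1, values2), z_pooled, prior)
}

#' Sample from the posterior of a component mean
#'
#' The marginal posterior of a component mean given the partition is a
#' generalised Student's t: `t_{a_k}(m_k, b_k / (a_k s_k))`, i.e. a
#' standard t with `a_k` degrees of freedom scaled by
#' `sqrt(b_k / (a_k s_k))` and shifted by `m_k`.
#'
#' @param post An [ng_posterior_params()] object.
#' @param n_draws Number of posterior draws.
#' @param seed Optional integer seed for reproducibility.
#'
#' @return Numeric vector of `n_draws` posterior samples.
#' @export
sample_component_mean_posterior <- function(post, n_draws, seed = NULL) {
  stopifnot(inherits(post, "ng_posterior"), n_draws >= 1)
  if (post$a_k <= 0) stop("degrees of freedom `a_k` must be positive",
                          call. = FALSE)
  if (!is.null(seed)) {
    old <- .save_rng_state()
    on.exit(.restore_rng_state(old))
    set.seed(seed)
  }
  post$m_k + sqrt(post$b_k / (post$a_k * post$s_k)) * rt(n_draws, df = post$a_k)
}

.save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
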