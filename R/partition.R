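#' Options controlling partition estimation
#'
#' Tuning constants for the per-gene partition estimator: a BIC-optimal
#' univariate normal mixture with at most `k_max` components, refined by a
#' split (from K = 1) or merge (from K >= 2) step gated by the bimodality
#' index and by outlier filters on component size and variance.
#'
#' @param k_max Maximum number of mixture components (default 5).
#' @param min_component_size Components with fewer cells than this are
#'   treated as outlier artefacts and merged away; the same cutoff defines
#'   which components are counted during classification (default 3).
#' @param merge_variance_ratio A component whose variance exceeds this
#'   multiple of any other component's variance forces a merge (default 20).
#' @param split_variance_ratio A proposed split is suppressed when one new
#'   component's variance exceeds this multiple of another's (default 10).
#' @param bi_thresholds Named numeric vector mapping sample sizes to
#'   bimodality-index cutoffs; thresholds at other sizes are interpolated
#'   linearly in `log(n)` and clamped at the ends. Defaults are calibrated
#'   by [calibrate_bi_thresholds()] to a 5% false-split rate on unimodal
#'   normal data.
#'
#' @return An object of class `partition_options`.
#' @export
partition_options <- function(k_max = 5,
                              min_component_size = 3,
                              merge_variance_ratio = 20,
                              split_variance_ratio = 10,
                              bi_thresholds = bi_threshold_defaults()) {
  stopifnot(k_max >= 1, min_component_size >= 1,
            merge_variance_ratio > 0, split_variance_ratio > 0,
            length(bi_thresholds) >= 1, all(bi_thresholds > 0),
            !is.null(names(bi_thresholds)))
  structure(list(k_max = as.integer(k_max),
                 min_component_size = as.integer(min_component_size),
                 merge_variance_ratio = merge_variance_ratio,
                 split_variance_ratio = split_variance_ratio,
                 bi_thresholds = bi_thresholds[order(as.numeric(names(bi_thresholds)))]),
            class = "partition_options")
}

#' Default bimodality-index cutoffs by sample size
#'
#' Constants produced by `calibrate_bi_thresholds()` with its default
#' settings (20,000 unimodal replicates per size, 5% target false-split
#' rate, seed 20160101).
#'
#' @return Named numeric vector; names are sample sizes.
#' @export
bi_threshold_defaults <- function() {
  c(`25` = 3.03, `50` = 2.70, `100` = 2.62, `200` = 2.64, `500` = 2.68)
}

.bi_table <- function(opts) {
  list(n = as.numeric(names(opts$bi_thresholds)),
       cut = as.numeric(opts$bi_thresholds))
}

#' Bimodality index of a pair of components
#'
#' `BI = 2 * sqrt(n1 n2 / (n1 + n2)^2) * |mu1 - mu2| / sigma` where `sigma`
#' is a conservatively estimated common within-component standard
#' deviation (the estimator uses the maximum SD across components).
#'
#' @param n1,n2 Component sizes (cells).
#' @param mu1,mu2 Component means.
#' @param sigma Common within-component standard deviation (> 0).
#'
#' @return The bimodality index.
#' @export
#' @examples
#' bimodality_index(10, 10, 0, 2, 1) # 2
bimodality_index <- function(n1, n2, mu1, mu2, sigma) {
  stopifnot(n1 >= 1, n2 >= 1)
  if (sigma <= 0) stop("`sigma` must be positive", call. = FALSE)
  2 * sqrt(n1 * n2 / (n1 + n2)^2) * abs(mu1 - mu2) / sigma
}

#' BIC-optimal univariate normal mixture
#'
#' Fits unequal-variance normal mixtures with K = 1, ..., `k_max` by EM
#' (deterministic quantile-block and largest-gap initialisations) and picks
#' K by lowest BIC; ties go to the smaller K. The feasible K is capped at
#' the number of distinct values and at `floor(n / min_component_size)`.
#'
#' @param values Numeric vector of (log-scale) expression values.
#' @param k_max Maximum K.
#' @param min_component_size Size cap used in the feasibility bound.
#'
#' @return A [new_partition()] with attributes `mean`, `var`, `weight`,
#'   `loglik`.
#' @export
fit_bic_mixture <- function(values, k_max = 5, min_component_size = 3) {
  stopifnot(length(values) >= 1, all(is.finite(values)))
  f <- .bic_mixture_cpp(as.numeric(values), as.integer(k_max),
                        as.integer(min_component_size))
  p <- new_partition(f$labels)
  attr(p, "mean") <- f$mean
  attr(p, "var") <- f$var
  attr(p, "weight") <- f$weight
  attr(p, "loglik") <- f$loglik
  p
}

#' Split/merge refinement of a mixture partition
#'
#' Applies the multi-modality gate to a BIC-selected partition: from K = 1
#' a two-component split is proposed and kept only when all (mean-adjacent)
#' component pairs pass the sample-size-specific bimodality-index cutoff,
#' no proposed component variance exceeds `split_variance_ratio` times
#' another's, and every component keeps at least `min_component_size`
#' cells. From K >= 2 the K-component fit is kept only under the same BI
#' gate; otherwise a (K-1)-component refit replaces it. A merge is forced
#' regardless of BI when a component variance exceeds
#' `merge_variance_ratio` times another's or a component falls below the
#' minimum size. The step is iterated to a fixed point, so the operation is
#' idempotent.
#'
#' @param values Numeric vector the partition was fitted to.
#' @param partition A [new_partition()] (typically from [fit_bic_mixture()]).
#' @param opts A [partition_options()].
#'
#' @return A refined [new_partition()].
#' @export
split_merge_refine <- function(values, partition, opts = partition_options()) {
  stopifnot(inherits(opts, "partition_options"))
  labels <- if (inherits(partition, "dd_partition")) partition$labels else
    new_partition(partition)$labels
  stopifnot(length(values) == length(labels))
  bt <- .bi_table(opts)
  new_partition(.refine_cpp(as.numeric(values), as.integer(labels),
                            opts$min_component_size,
                            opts$merge_variance_ratio,
                            opts$split_variance_ratio, bt$n, bt$cut))
}

#' Estimate the partition of one gene's values
#'
#' Convenience wrapper: [fit_bic_mixture()] followed by
#' [split_merge_refine()].
#'
#' @inheritParams split_merge_refine
#' @return A [new_partition()].
#' @export
estimate_partition <- function(values, opts = partition_options()) {
  split_merge_refine(values, fit_bic_mixture(values, opts$k_max,
                                             opts$min_component_size), opts)
}

#' Number of components meeting a minimum size
#'
#' @param partition A [new_partition()].
#' @param min_size Minimum cells per counted component (default 3).
#'
#' @return Integer count of components with at least `min_size` cells.
#' @export
effective_component_count <- function(partition, min_size = 3) {
  stopifnot(inherits(partition, "dd_partition"))
  sum(partition$sizes >= min_size)
}

#' Calibrate bimodality-index cutoffs
#'
#' Simulates unimodal standard-normal samples at each size, fits a forced
#' two-component mixture, and records its bimodality index; the cutoff is
#' the `1 - fp_target` quantile, so a unimodal gene is falsely split at
#' rate `fp_target` under clean normal data. Used to generate the shipped
#' [bi_threshold_defaults()].
#'
#' @param sizes Sample sizes to calibrate.
#' @param n_sim Null replicates per size.
#' @param fp_target Target false-split rate.
#' @param seed Integer seed.
#'
#' @return Named numeric vector of cutoffs.
#' @export
calibrate_bi_thresholds <- function(sizes = c(25, 50, 100, 200, 500),
                                    n_sim = 20000, fp_target = 0.05,
                                    seed = 20160101) {
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  set.seed(seed)
  out <- vapply(sizes, function(n) {
    bi <- vapply(seq_len(n_sim), function(i) {
      x <- rnorm(n)
      f <- .em_fit_cpp(x, 2L)
      if (!isTRUE(f$ok)) return(NA_real_)
      sz <- tabulate(f$labels, nbins = 2L)
      if (any(sz < 1)) return(NA_real_)
      sds <- vapply(1:2, function(k) {
        v <- x[f$labels == k]
        if (length(v) > 1) sd(v) else 0
      }, numeric(1))
      sigma <- max(sds)
      if (sigma <= 0) return(NA_real_)
      bimodality_index(sz[1], sz[2], mean(x[f$labels == 1]),
                       mean(x[f$labels == 2]), sigma)
    }, numeric(1))
    as.numeric(quantile(bi, 1 - fp_target, na.rm = TRUE))
  }, numeric(1))
  names(out) <- as.character(sizes)
  out
}

#' Census of per-gene modality
#'
#' Estimates the partition of each gene's log-transformed nonzero values
#' and tabulates how many genes are best described by 1, 2, or 3+ modes
#' (components with at least `min_component_size` cells). Genes detected in
#' fewer than `min_detection` of cells are excluded.
#'
#' @param counts Genes x cells matrix of non-negative expression values.
#' @param min_detection Minimum nonzero fraction for a gene to be censused.
#' @param opts A [partition_options()].
#'
#' @return A tibble with columns `modes` ("1", "2", "3+"), `n_genes`, and
#'   `proportion`.
#' @export
modality_census <- function(counts, min_detection = 0.25,
                            opts = partition_options()) {
  counts <- .as_counts_matrix(counts)
  if (nrow(counts) == 0) {
    return(tibble::tibble(modes = character(), n_genes = integer(),
                          proportion = numeric()))
  }
  detected <- rowMeans(counts > 0) >= min_detection
  ks <- vapply(which(detected), function(g) {
    y <- log(counts[g, counts[g, ] > 0])
    if (length(y) < opts$min_component_size) return(NA_integer_)
    effective_component_count(estimate_partition(y, opts),
                              opts$min_component_size)
  }, integer(1))
  ks <- ks[!is.na(ks) & ks >= 1]
  if (length(ks) == 0) {
    return(tibble::tibble(modes = character(), n_genes = integer(),
                          proportion = numeric()))
  }
  bin <- factor(ifelse(ks >= 3, "3+", as.character(ks)),
                levels = c("1", "2", "3+"))
  tab <- table(bin)
  tibble::tibble(modes = names(tab), n_genes = as.integer(tab),
                 proportion = as.numeric(tab) / length(ks))
}
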