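#' Evaluate a fit against simulation ground truth
#'
#' Summarises detection and classification performance of a
#' differential-distribution analysis on simulated data: power by true
#' category with the observed false discovery rate, the correct
#' classification rate among detected genes by category, and the same rate
#' stratified by component mean distance.
#'
#' @param results Per-gene results tibble (from `tidy(dd_test(...))`) with
#'   columns `gene`, `significant`, `category`.
#' @param truth Ground-truth tibble from [simulate_dd_data()] with columns
#'   `gene`, `category`, `delta_mu`.
#'
#' @return A list of tibbles (`power`, `classification`,
#'   `classification_by_delta`) of class `dd_evaluation`. `power` contains
#'   one row per true DD category plus an `observed_fdr` attribute column
#'   in the `fdr` tibble field.
#' @export
evaluate_run <- function(results, truth) {
  stopifnot(all(c("gene", "significant") %in% names(results)),
            all(c("gene", "category") %in% names(truth)))
  if (!all(results$gene %in% truth$gene)) {
    stop("results contain genes absent from the truth table", call. = FALSE)
  }
  joined <- dplyr::inner_join(
    results,
    dplyr::rename(truth, true_category = "category"),
    by = "gene")
  dd_cats <- c("DE", "DP", "DM", "DB")
  power <- joined |>
    dplyr::filter(.data$true_category %in% dd_cats) |>
    dplyr::group_by(true_category = factor(.data$true_category,
                                           levels = dd_cats)) |>
    dplyr::summarise(n = dplyr::n(),
                     n_detected = sum(.data$significant),
                     power = mean(.data$significant),
                     .groups = "drop")
  n_sig <- sum(joined$significant)
  n_false <- sum(joined$significant & joined$true_category %in% c("EE", "EP"))
  fdr <- tibble::tibble(n_significant = n_sig, n_false_positive = n_false,
                        observed_fdr = if (n_sig > 0) n_false / n_sig else 0)
  classification <- joined |>
    dplyr::filter(.data$true_category %in% dd_cats, .data$significant) |>
    dplyr::group_by(true_category = factor(.data$true_category,
                                           levels = dd_cats)) |>
    dplyr::summarise(
      n_detected = dplyr::n(),
      correct_rate = mean(.data$category == .data$true_category,
                          na.rm = FALSE),
      .groups = "drop")
  by_delta <- joined |>
    dplyr::filter(.data$true_category %in% c("DP", "DM", "DB"),
                  .data$significant, !is.na(.data$delta_mu)) |>
    dplyr::group_by(true_category = factor(.data$true_category,
                                           levels = c("DP", "DM", "DB")),
                    delta_mu = .data$delta_mu) |>
    dplyr::summarise(
      n_detected = dplyr::n(),
      correct_rate = mean(.data$category == .data$true_category),
      .groups = "drop")
  structure(list(power = power, fdr = fdr, classification = classification,
                 classification_by_delta = by_delta),
            class = "dd_evaluation")
}

#' @export
print.dd_evaluation <- function(x, ...) {
  cat("Power by true category:\n")
  print(x$power)
  cat("\nObserved FDR:\n")
  print(x$fdr)
  cat("\nCorrect classification among detected genes:\n")
  print(x$classification)
  invisible(x)
}

#' Rate of correct component-number detection on simulated data
#'
#' For each simulated gene and condition, estimates the partition of the
#' log nonzero values and compares the number of counted components
#' (at least `min_component_size` cells) with the generative modality
#' (unimodal or bimodal). Genes failing the detection filter are excluded.
#' Bimodal results are stratified by component mean distance.
#'
#' @param sim A dataset from [simulate_dd_data()].
#' @param opts A [partition_options()].
#' @param min_detection Detection filter (default 0.25).
#' @param normalize Normalize with a positive-count pseudo-reference before
#'   fitting.
#'
#' @return A tibble with columns `modality`, `delta_mu` (`NA` for
#'   unimodal), `n`, `correct_rate`.
#' @export
k_detection_rates <- function(sim, opts = partition_options(),
                              min_detection = 0.25, normalize = TRUE) {
  counts <- sim$counts
  cond <- sim$condition
  truth <- sim$truth
  keep <- detection_filter(counts, cond, min_detection)
  counts <- counts[keep, , drop = FALSE]
  truth <- truth[match(keep, truth$gene), ]
  if (normalize) {
    sf <- median_ratio_size_factors(counts, type = "poscounts")
    counts <- sweep(counts, 2, sf, "/")
  }
  true_k <- function(category, cond_idx) {
    switch(category,
           EE = 1L, DE = 1L,
           EP = 2L, DP = 2L,
           DM = if (cond_idx == 1L) 1L else 2L,
           DB = if (cond_idx == 1L) 1L else 2L)
  }
  rows <- list()
  for (g in seq_len(nrow(counts))) {
    for (cc in 1:2) {
      v <- counts[g, cond == cc]
      y <- log(v[v > 0])
      if (length(y) < opts$min_component_size) next
      k_est <- effective_component_count(estimate_partition(y, opts),
                                         opts$min_component_size)
      k_tru <- true_k(truth$category[g], cc)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        gene = truth$gene[g],
        modality = if (k_tru == 1L) "unimodal" else "bimodal",
        delta_mu = if (k_tru == 2L) truth$delta_mu[g] else NA_real_,
        correct = k_est == k_tru)
    }
  }
  dplyr::bind_rows(rows) |>
    dplyr::group_by(.data$modality, .data$delta_mu) |>
    dplyr::summarise(n = dplyr::n(), correct_rate = mean(.data$correct),
                     .groups = "drop")
}
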