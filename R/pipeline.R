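#' Test all genes for differential distributions between two conditions
#'
#' Runs the full analysis on a genes x cells expression matrix: detection
#' filtering, median-of-ratios normalization, a permutation test of the
#' Bayes factor score per gene (with partition estimates re-fitted inside
#' each permutation), BH control of the false discovery rate, the
#' mean-shift and Fisher differential-proportion rescue steps,
#' classification of significant genes into DE / DP / DM / DB / NC, and a
#' differential-proportion-of-zeroes (DZ) screen of the remaining genes.
#'
#' @param counts Genes x cells matrix (or data frame) of non-negative
#'   expression values. Rows are genes, columns are cells.
#' @param condition Per-cell condition labels; exactly two distinct values.
#' @param covariate Optional per-cell numeric covariate for residual
#'   permutation, or the string `"detection"` for the cellular detection
#'   rate.
#' @param n_perm Permutations per gene (default 1000).
#' @param fdr Target false discovery rate (default 0.05).
#' @param prior An [ng_prior()].
#' @param opts A [partition_options()].
#' @param normalize Apply [median_ratio_size_factors()] before modelling
#'   (disable for pre-normalized input such as FPKM/TPM).
#' @param size_factor_type Passed to [median_ratio_size_factors()].
#' @param min_detection Per-condition detection filter (default 0.25).
#' @param rescue Apply the mean-shift and Fisher DP rescue steps.
#' @param dz Run the differential-proportion-of-zeroes screen.
#' @param dz_threshold Adjusted-p cutoff for DZ calls (default 0.025).
#' @param n_overlap_draws Posterior draws per component during
#'   classification (default 10000).
#' @param seed Integer seed; results are reproducible given
#'   `(seed, n_perm, gene order)`.
#' @param verbose Print progress.
#'
#' @return An object of class `dd_fit`. Use [tidy()] for the per-gene
#'   results table, [glance()] for a one-row summary, [autoplot()] for an
#'   overview figure, and [gene_memberships()] for per-cell component
#'   assignments.
#' @export
dd_test <- function(counts, condition, covariate = NULL,
                    n_perm = 1000, fdr = 0.05,
                    prior = ng_prior(), opts = partition_options(),
                    normalize = TRUE, size_factor_type = "ratio",
                    min_detection = 0.25,
                    rescue = TRUE, dz = TRUE, dz_threshold = 0.025,
                    n_overlap_draws = 10000,
                    seed = 1L, verbose = FALSE) {
  counts <- .as_counts_matrix(counts)
  cond <- .as_condition(condition, ncol(counts))
  detection_rate <- colMeans(counts > 0)

  keep <- detection_filter(counts, cond, min_detection)
  counts_f <- counts[keep, , drop = FALSE]
  if (nrow(counts_f) == 0) stop("no gene passes the detection filter",
                                call. = FALSE)
  if (normalize) {
    sf <- median_ratio_size_factors(counts_f, type = size_factor_type)
    norm <- sweep(counts_f, 2, sf, "/")
  } else {
    sf <- setNames(rep(1, ncol(counts_f)), colnames(counts_f))
    norm <- counts_f
  }
  views <- make_gene_views(norm, cond, covariate)

  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  set.seed(seed)
  n_genes <- length(views)
  scores <- p_perm <- rep(NA_real_, n_genes)
  testable <- logical(n_genes)
  parts <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    res <- permutation_test(views[[g]], n_perm, prior, opts)
    scores[g] <- res$score
    p_perm[g] <- res$p_perm
    testable[g] <- res$testable
    parts[[g]] <- res[c("z1", "z2", "z_pooled")]
    if (verbose && g %% 100 == 0) message("tested ", g, "/", n_genes)
  }

  q_value <- rep(NA_real_, n_genes)
  q_value[testable] <- bh_adjust(p_perm[testable])
  significant <- !is.na(q_value) & q_value <= fdr
  rescue_source <- rep("none", n_genes)

  comp_counts <- t(vapply(seq_len(n_genes), function(g) {
    if (!testable[g]) return(c(NA_integer_, NA_integer_, NA_integer_))
    c(effective_component_count(parts[[g]]$z1, opts$min_component_size),
      effective_component_count(parts[[g]]$z2, opts$min_component_size),
      effective_component_count(parts[[g]]$z_pooled, opts$min_component_size))
  }, integer(3)))

  category <- rep(NA_character_, n_genes)
  if (rescue) {
    cand <- which(testable & !significant)
    if (length(cand)) {
      ms <- mean_shift_rescue(views[cand], fdr_target = fdr)
      hit <- cand[ms$rescued]
      significant[hit] <- TRUE
      rescue_source[hit] <- "mean_shift"
    }
    cand <- which(testable & !significant)
    for (g in cand) {
      if (isTRUE(fisher_dp_rescue(views[[g]], parts[[g]]$z1, parts[[g]]$z2,
                                  parts[[g]]$z_pooled,
                                  opts$min_component_size))) {
        significant[g] <- TRUE
        rescue_source[g] <- "fisher_dp"
        category[g] <- "DP"
      }
    }
  }

  to_classify <- which(significant & is.na(category))
  for (g in to_classify) {
    cs <- component_summary(views[[g]], parts[[g]]$z1, parts[[g]]$z2,
                            parts[[g]]$z_pooled, prior,
                            opts$min_component_size)
    category[g] <- classify_dd_gene(
      cs, n_draws = n_overlap_draws,
      seed = (seed + 104729 * g) %% 2147483647L)
  }

  gene_names <- names(views)
  dz_tbl <- tibble::tibble(gene = gene_names, dz_p = NA_real_,
                           dz_q = NA_real_, dz = FALSE)
  if (dz) {
    eligible <- which(!significant)
    if (length(eligible)) {
      pz <- vapply(eligible, function(g) {
        dz_test(views[[g]]$zero_flag, cond, detection_rate)
      }, numeric(1))
      names(pz) <- gene_names[eligible]
      calls <- dz_call_set(pz, dz_threshold)
      dz_tbl$dz_p[eligible] <- calls$dz_p
      dz_tbl$dz_q[eligible] <- calls$dz_q
      dz_tbl$dz[eligible] <- calls$dz
    }
  }

  results <- tibble::tibble(
    gene = gene_names,
    n_nonzero_1 = vapply(views, function(v) {
      sum(!v$zero_flag & v$condition == 1L)
    }, integer(1)),
    n_nonzero_2 = vapply(views, function(v) {
      sum(!v$zero_flag & v$condition == 2L)
    }, integer(1)),
    testable = testable,
    score = scores,
    p_perm = p_perm,
    q_value = q_value,
    significant = significant,
    rescue_source = rescue_source,
    c1 = comp_counts[, 1],
    c2 = comp_counts[, 2],
    c_oa = comp_counts[, 3],
    category = category,
    dz_p = dz_tbl$dz_p,
    dz_q = dz_tbl$dz_q,
    dz = dz_tbl$dz
  )

  structure(list(results = results, partitions = setNames(parts, gene_names),
                 views = views, norm_counts = norm, size_factors = sf,
                 condition = cond, prior = prior, opts = opts,
                 n_perm = n_perm, fdr = fdr, seed = seed,
                 n_genes_input = nrow(counts), dz_threshold = dz_threshold),
            class = "dd_fit")
}

#' @export
print.dd_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<dd_fit> %d genes in, %d tested (%d permutations), %d significant at FDR %.3g\n",
    x$n_genes_input, g$n_tested, x$n_perm, g$n_significant, x$fdr))
  cats <- table(factor(x$results$category[x$results$significant],
                       levels = c("DE", "DP", "DM", "DB", "NC")))
  cat("  categories:", paste(names(cats), cats, sep = "=", collapse = " "),
      " DZ:", sum(x$results$dz), "\n")
  invisible(x)
}

#' Tidy the per-gene results of a differential-distribution fit
#'
#' @param x A `dd_fit`.
#' @param ... Unused.
#' @return A tibble with one row per retained gene: score, permutation
#'   p-value, BH-adjusted q-value, significance flag, rescue source,
#'   component counts, category, and DZ results.
#' @export
tidy.dd_fit <- function(x, ...) x$results

#' One-row summary of a differential-distribution fit
#'
#' @param x A `dd_fit`.
#' @param ... Unused.
#' @return A one-row tibble of gene counts by outcome.
#' @export
glance.dd_fit <- function(x, ...) {
  r <- x$results
  tibble::tibble(
    n_input = x$n_genes_input,
    n_retained = nrow(r),
    n_tested = sum(r$testable),
    n_significant = sum(r$significant),
    n_de = sum(r$category == "DE", na.rm = TRUE),
    n_dp = sum(r$category == "DP", na.rm = TRUE),
    n_dm = sum(r$category == "DM", na.rm = TRUE),
    n_db = sum(r$category == "DB", na.rm = TRUE),
    n_nc = sum(r$category == "NC", na.rm = TRUE),
    n_dz = sum(r$dz),
    n_perm = x$n_perm,
    fdr = x$fdr
  )
}

#' Overview plot of a differential-distribution fit
#'
#' Bar chart of significant genes by category (plus DZ calls).
#'
#' @param object A `dd_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dd_fit <- function(object, ...) {
  r <- object$results
  counts <- c(table(factor(r$category[r$significant],
                           levels = c("DE", "DP", "DM", "DB", "NC"))),
              DZ = sum(r$dz))
  df <- tibble::tibble(category = factor(names(counts), levels = names(counts)),
                       n = as.integer(counts))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "genes",
                  title = "Differentially distributed genes by pattern") +
    ggplot2::theme_minimal()
}

#' Per-cell component memberships of one gene
#'
#' @param fit A `dd_fit`.
#' @param gene Gene name.
#' @return Tibble with one row per cell: `cell`, `condition`, `zero`,
#'   `component` (within-condition component index of nonzero cells, `NA`
#'   for zeroes), and `component_pooled`.
#' @export
gene_memberships <- function(fit, gene) {
  stopifnot(inherits(fit, "dd_fit"), gene %in% names(fit$views))
  v <- fit$views[[gene]]
  p <- fit$partitions[[gene]]
  nz <- !v$zero_flag
  comp <- comp_pooled <- rep(NA_integer_, length(nz))
  if (!is.null(p$z1)) {
    comp[nz & v$condition == 1L] <- p$z1$labels
    comp[nz & v$condition == 2L] <- p$z2$labels
    comp_pooled[nz] <- p$z_pooled$labels
  }
  tibble::tibble(cell = colnames(fit$norm_counts),
                 condition = v$condition, zero = v$zero_flag,
                 component = comp, component_pooled = comp_pooled)
}

#' Violin plot of one gene's expression by condition
#'
#' Log-scale nonzero expression per condition with jittered points shaped
#' by the within-condition component membership.
#'
#' @param fit A `dd_fit`.
#' @param gene Gene name.
#' @return A ggplot object.
#' @export
plot_gene <- function(fit, gene) {
  stopifnot(inherits(fit, "dd_fit"), gene %in% names(fit$views))
  v <- fit$views[[gene]]
  mem <- gene_memberships(fit, gene)
  nz <- !v$zero_flag
  df <- tibble::tibble(
    condition = factor(v$condition[nz]),
    log_expression = v$nonzero_log,
    component = factor(mem$component[nz]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition,
                                   y = .data$log_expression)) +
    ggplot2::geom_violin(fill = "grey90", colour = "grey60") +
    ggplot2::geom_jitter(ggplot2::aes(shape = .data$component),
                         width = 0.15, height = 0, alpha = 0.8) +
    ggplot2::labs(title = gene, x = "condition",
                  y = "log nonzero expression") +
    ggplot2::theme_minimal()
}

#' Write the results table to a delimited file
#'
#' @param fit A `dd_fit`.
#' @param path Output file path.
#' @param sep Field separator (default tab).
#' @return The path, invisibly.
#' @export
write_results <- function(fit, path, sep = "\t") {
  stopifnot(inherits(fit, "dd_fit"))
  utils::write.table(tidy(fit), path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
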