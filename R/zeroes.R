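#' Test for a differential proportion of zeroes
#'
#' Logistic regression of the per-cell zero indicator on condition,
#' adjusted for the cellular detection rate; the p-value is the
#' likelihood-ratio chi-square for the condition term. With complete or
#' quasi-complete separation the asymptotic fit is unreliable, so the
#' p-value falls back to Fisher's exact test on the 2 x 2
#' zero-by-condition table (with a warning).
#'
#' @param zero_flag Logical per-cell indicator of zero expression.
#' @param condition Per-cell condition labels (two conditions).
#' @param detection_rate Optional per-cell detection rate covariate.
#'
#' @return A p-value, or `NA` when the gene is untestable (all cells zero
#'   or none).
#' @export
dz_test <- function(zero_flag, condition, detection_rate = NULL) {
  cond <- .as_condition(condition, length(zero_flag))
  z <- as.logical(zero_flag)
  if (all(z) || !any(z)) return(NA_real_)
  dat <- data.frame(z = z, cond = factor(cond))
  if (!is.null(detection_rate)) {
    dat$det <- detection_rate
    full_f <- z ~ cond + det
    null_f <- z ~ det
  } else {
    full_f <- z ~ cond
    null_f <- z ~ 1
  }
  separated <- FALSE
  fit_full <- withCallingHandlers(
    glm(full_f, family = binomial(), data = dat),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  separated <- separated ||
    any(fit_full$fitted.values < 1e-8 | fit_full$fitted.values > 1 - 1e-8)
  if (separated) {
    warning("separation in logistic fit; using exact test fallback",
            call. = FALSE)
    return(fisher.test(table(z, cond))$p.value)
  }
  fit_null <- suppressWarnings(glm(null_f, family = binomial(), data = dat))
  dev <- fit_null$deviance - fit_full$deviance
  df <- fit_null$df.residual - fit_full$df.residual
  if (df < 1) return(NA_real_)
  pchisq(dev, df = df, lower.tail = FALSE)
}

#' Call genes with a differential proportion of zeroes
#'
#' BH-adjusts the [dz_test()] p-values of the eligible genes (those not
#' already differentially distributed on their nonzero values) and flags
#' genes with adjusted p below the cutoff.
#'
#' @param p_values Named numeric vector of raw p-values (`NA` allowed for
#'   untestable genes).
#' @param threshold Adjusted-p cutoff (default 0.025).
#'
#' @return Tibble with columns `gene`, `dz_p`, `dz_q`, `dz`.
#' @export
dz_call_set <- function(p_values, threshold = 0.025) {
  if (length(p_values) == 0) {
    return(tibble::tibble(gene = character(), dz_p = numeric(),
                          dz_q = numeric(), dz = logical()))
  }
  nm <- names(p_values)
  if (is.null(nm)) nm <- as.character(seq_along(p_values))
  q <- rep(NA_real_, length(p_values))
  ok <- !is.na(p_values)
  q[ok] <- bh_adjust(p_values[ok])
  tibble::tibble(gene = nm, dz_p = as.numeric(p_values), dz_q = q,
                 dz = !is.na(q) & q < threshold)
}
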