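.as_counts_matrix <- function(counts) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (inherits(counts, "Matrix")) counts <- as.matrix(counts)
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("`counts` must be a numeric genes x cells matrix", call. = FALSE)
  }
  if (any(counts < 0, na.rm = TRUE) || anyNA(counts)) {
    stop("`counts` must be non-negative and free of missing values",
         call. = FALSE)
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("gene%05d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("cell%04d", seq_len(ncol(counts)))
  }
  counts
}

#' Median-of-ratios size factors
#'
#' Per-cell scaling factors computed as the median of each cell's count
#' ratios to the per-gene geometric mean, over genes with positive counts
#' in every cell. Factors are rescaled to have geometric mean 1, so
#' normalized values are on the scale of a typical cell.
#'
#' @param counts Genes x cells matrix of non-negative counts.
#' @param type `"ratio"` (default) uses only genes positive in all cells
#'   and errors when none exist; `"poscounts"` computes the geometric mean
#'   over positive counts only (a pseudo-reference fallback for very sparse
#'   data).
#'
#' @return Named numeric vector of per-cell size factors.
#' @export
median_ratio_size_factors <- function(counts, type = c("ratio", "poscounts")) {
  counts <- .as_counts_matrix(counts)
  type <- match.arg(type)
  if (type == "ratio") {
    log_geo <- rowMeans(log(counts))
    use <- is.finite(log_geo)
    if (!any(use)) {
      stop(paste0(
        "no gene has positive counts in every cell; rerun with ",
        "type = \"poscounts\" to use a pseudo-reference over positive ",
        "counts only"), call. = FALSE)
    }
  } else {
    log_geo <- apply(counts, 1, function(r) {
      pos <- r > 0
      if (!any(pos)) return(NA_real_)
      mean(log(r[pos]))
    })
    use <- is.finite(log_geo) & rowSums(counts > 0) > ncol(counts) / 2
    if (!any(use)) use <- is.finite(log_geo)
    if (!any(use)) stop("all genes are entirely zero", call. = FALSE)
  }
  sf <- apply(counts[use, , drop = FALSE], 2, function(col) {
    r <- col / exp(log_geo[use])
    median(r[col > 0 | type == "ratio"])
  })
  if (any(!is.finite(sf)) || any(sf <= 0)) {
    stop("a cell has no positive counts among reference genes", call. = FALSE)
  }
  sf / exp(mean(log(sf)))
}

#' Filter genes by detection rate
#'
#' Keeps genes whose nonzero fraction is at least `min_rate` in *both*
#' conditions (a gene weakly detected in either condition is dropped).
#'
#' @param counts Genes x cells matrix.
#' @param condition Per-cell condition labels (exactly two distinct values).
#' @param min_rate Minimum nonzero fraction per condition (default 0.25).
#'
#' @return Character vector of retained gene names.
#' @export
detection_filter <- function(counts, condition, min_rate = 0.25) {
  counts <- .as_counts_matrix(counts)
  cond <- .as_condition(condition, ncol(counts))
  keep <- rowMeans(counts[, cond == 1L, drop = FALSE] > 0) >= min_rate &
    rowMeans(counts[, cond == 2L, drop = FALSE] > 0) >= min_rate
  rownames(counts)[keep]
}

.as_condition <- function(condition, n_cells) {
  if (length(condition) != n_cells) {
    stop("`condition` must have one label per cell", call. = FALSE)
  }
  f <- factor(condition)
  if (nlevels(f) != 2) {
    stop("exactly two conditions are required", call. = FALSE)
  }
  as.integer(f)
}

#' Per-gene views of zero pattern and log nonzero values
#'
#' Splits each gene of a normalized matrix into the per-cell zero indicator
#' and the log-transformed nonzero values that feed the mixture model.
#' Zeroes are defined on the input values (size-factor division preserves
#' them).
#'
#' @param norm_counts Normalized genes x cells matrix.
#' @param condition Per-cell condition labels (two conditions).
#' @param covariate Optional per-cell numeric covariate; the string
#'   `"detection"` uses each cell's detection rate (fraction of genes with
#'   nonzero expression).
#' @param log_base Base of the log transform (default natural log).
#'
#' @return Named list of gene views; each is a list with `nonzero_log`,
#'   `zero_flag`, `condition`, `covariate` (possibly `NULL`), and
#'   `testable` (each condition has nonzero cells).
#' @export
make_gene_views <- function(norm_counts, condition, covariate = NULL,
                            log_base = exp(1)) {
  counts <- .as_counts_matrix(norm_counts)
  cond <- .as_condition(condition, ncol(counts))
  if (identical(covariate, "detection")) {
    covariate <- colMeans(counts > 0)
  }
  if (!is.null(covariate) && length(covariate) != ncol(counts)) {
    stop("`covariate` must have one value per cell", call. = FALSE)
  }
  lapply(setNames(seq_len(nrow(counts)), rownames(counts)), function(g) {
    v <- counts[g, ]
    nz <- v > 0
    list(nonzero_log = log(v[nz], base = log_base),
         zero_flag = !nz,
         condition = cond,
         covariate = covariate,
         testable = all(tabulate(cond[nz], nbins = 2L) > 0))
  })
}

#' Read a counts matrix from disk
#'
#' Reads either a dense delimited genes x cells table (gene names in the
#' first column, cell names in the header) or a matrix-market sparse
#' triplet accompanied by `<stem>.rownames` / `<stem>.colnames` text files.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"delim"`, or `"mtx"`.
#' @param sep Field separator for delimited input.
#'
#' @return A dense genes x cells numeric matrix.
#' @export
read_counts <- function(path, format = c("auto", "delim", "mtx"), sep = "\t") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "delim"
  }
  if (format == "mtx") {
    if (!requireNamespace("Matrix", quietly = TRUE)) {
      stop("reading matrix-market input requires the Matrix package",
           call. = FALSE)
    }
    m <- as.matrix(Matrix::readMM(path))
    stem <- sub("\\.mtx$", "", path, ignore.case = TRUE)
    rn <- paste0(stem, ".rownames")
    cn <- paste0(stem, ".colnames")
    if (file.exists(rn)) rownames(m) <- readLines(rn)
    if (file.exists(cn)) colnames(m) <- readLines(cn)
    return(.as_counts_matrix(m))
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE)
  .as_counts_matrix(as.matrix(df))
}
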