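# Probe-set summarization, log transform, and array quality control.

#' Summarize probes to probe sets
#'
#' Collapses a probe-level matrix to one row per probe set, taking the
#' per-array median (default) or mean over each set's probes. The median is
#' the default because it is robust to a single biased probe; with the
#' generator's symmetric probe biases both summarizers are unbiased.
#'
#' @param probes Probe-level matrix (probes x arrays).
#' @param map Probe map with columns `probe_id`, `probeset_id`.
#' @param method `"median"` or `"mean"`.
#' @return Probe-set x array matrix (rows ordered by probe-set id).
#' @export
summarize_probesets <- function(probes, map, method = c("median", "mean")) {
  method <- match.arg(method)
  stopifnot_numeric_matrix(probes, "probes")
  idx <- match(rownames(probes), map$probe_id)
  if (anyNA(idx)) {
    offenders <- utils::head(rownames(probes)[is.na(idx)], 10)
    ifl_stop("validation", "unmapped probe(s): %s%s",
             paste(offenders, collapse = ", "),
             if (sum(is.na(idx)) > 10) sprintf(" (and %d more)", sum(is.na(idx)) - 10) else "")
  }
  f <- map$probeset_id[idx]
  fn <- if (method == "median") stats::median else mean
  sets <- split(seq_len(nrow(probes)), f)
  out <- t(vapply(sets, function(i) {
    if (length(i) == 1L) probes[i, ] else apply(probes[i, , drop = FALSE], 2, fn)
  }, numeric(ncol(probes))))
  colnames(out) <- colnames(probes)
  attr(out, "log2") <- attr(probes, "log2")
  out
}

#' Log2-transform an expression matrix
#'
#' @param matrix Expression matrix.
#' @param already_log If `TRUE` the matrix is returned unchanged (with the
#'   scale flag set); otherwise values must be strictly positive and log2 is
#'   applied exactly once.
#' @return Matrix on the log2 scale with attribute `log2 = TRUE`.
#' @export
log_transform <- function(matrix, already_log = FALSE) {
  if (already_log || isTRUE(attr(matrix, "log2"))) {
    attr(matrix, "log2") <- TRUE
    return(matrix)
  }
  bad <- which(matrix <= 0, arr.ind = TRUE)
  if (nrow(bad))
    ifl_stop("data", "non-positive value at (%s, %s) cannot be log-transformed",
             rownames(matrix)[bad[1, 1]], colnames(matrix)[bad[1, 2]])
  out <- log2(matrix)
  attr(out, "log2") <- TRUE
  out
}

#' Per-array quality-control statistics
#'
#' Computes, per array: median log2 intensity, interquartile range, median
#' pairwise inter-array correlation, and the first two principal-component
#' scores of the gene-centered expression matrix. This codifies the usual
#' visual QC (intensity box plots plus array PCA) in an automatable form.
#'
#' @param matrix Expression matrix (>= 3 arrays).
#' @return Data frame of class `qc_report` with one row per array and columns
#'   `array_id`, `median`, `iqr`, `median_correlation`, `pc1`, `pc2`,
#'   `flagged`, `reason`.
#' @export
array_qc_stats <- function(matrix) {
  stopifnot_numeric_matrix(matrix, "matrix")
  if (ncol(matrix) < 3L)
    ifl_stop("insufficient_data", "array QC needs >= 3 arrays, got %d", ncol(matrix))
  med <- apply(matrix, 2, stats::median)
  iqr <- apply(matrix, 2, stats::IQR)
  cc <- suppressWarnings(stats::cor(matrix))
  diag(cc) <- NA
  medcor <- apply(cc, 2, stats::median, na.rm = TRUE)
  medcor[is.na(medcor)] <- 1  # degenerate all-constant genes
  centered <- matrix - rowMeans(matrix)
  pc <- stats::prcomp(t(centered), center = FALSE, scale. = FALSE)
  scores <- pc$x
  pc1 <- if (ncol(scores) >= 1) scores[, 1] else rep(0, ncol(matrix))
  pc2 <- if (ncol(scores) >= 2) scores[, 2] else rep(0, ncol(matrix))
  structure(data.frame(array_id = colnames(matrix), median = med, iqr = iqr,
                       median_correlation = medcor, pc1 = pc1, pc2 = pc2,
                       flagged = FALSE, reason = "",
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("qc_report", "data.frame"))
}

#' Flag failed arrays
#'
#' An array fails QC if its median inter-array correlation falls below
#' `min_median_correlation`, or its PC1 score deviates by more than
#' `pc_mad_multiplier` times the MAD of PC1 scores (MAD floored at a small
#' epsilon so identical arrays are never flagged). When a sample sheet is
#' supplied, PC1 deviations are measured from the array's own treatment-group
#' median: PC1 routinely separates treatments, and the rule is meant to catch
#' isolated technical outliers, not biology. As a hard guard the rule refuses
#' to flag more than 25% of arrays: at that point the data, not individual
#' arrays, are suspect.
#'
#' @param report A [array_qc_stats()] report.
#' @param min_median_correlation Correlation threshold (default 0.8).
#' @param pc_mad_multiplier PC1 robust-outlier multiplier (default 5).
#' @param sheet Optional sample sheet; centers PC1 within treatment groups.
#' @return The report with `flagged` and `reason` filled in.
#' @export
flag_failed_arrays <- function(report, min_median_correlation = 0.8,
                               pc_mad_multiplier = 5, sheet = NULL) {
  if (!inherits(report, "qc_report"))
    ifl_stop("validation", "report must come from array_qc_stats()")
  low_cor <- report$median_correlation < min_median_correlation
  pc1 <- report$pc1
  if (!is.null(sheet)) {
    grp <- sheet$treatment[match(report$array_id, sheet$array_id)]
    if (anyNA(grp))
      ifl_stop("validation", "QC report contains arrays absent from the sample sheet")
    ctr <- stats::ave(pc1, grp, FUN = stats::median)
  } else {
    ctr <- stats::median(pc1)
  }
  madv <- stats::mad(pc1 - ctr, center = 0)
  eps <- 1e-8 * max(1, max(abs(pc1)))
  dev <- abs(pc1 - ctr)
  pc_out <- dev > pc_mad_multiplier * max(madv, eps)
  flagged <- low_cor | pc_out
  if (sum(flagged) > 0.25 * nrow(report))
    ifl_stop("qc_failure",
             "QC rule would flag %d of %d arrays (> 25%%); refusing — inspect the data",
             sum(flagged), nrow(report))
  reason <- character(nrow(report))
  reason[low_cor] <- sprintf("median inter-array correlation %.3f < %.3f",
                             report$median_correlation[low_cor], min_median_correlation)
  reason[pc_out & !low_cor] <- sprintf("PC1 deviates %.3g > %g x MAD",
                                       dev[pc_out & !low_cor], pc_mad_multiplier)
  reason[pc_out & low_cor] <- paste0(reason[pc_out & low_cor], "; PC1 outlier")
  report$flagged <- flagged
  report$reason <- reason
  report
}

#' Exclude flagged arrays
#'
#' Removes QC-flagged arrays from the matrix. If a sample sheet is supplied,
#' the surviving per-treatment sample sizes are reported and an error is
#' raised if any treatment drops below two arrays.
#'
#' @param matrix Expression (or probe-level) matrix.
#' @param report A flagged [array_qc_stats()] report for these arrays.
#' @param sheet Optional sample sheet for the per-treatment check.
#' @return The matrix without flagged arrays.
#' @export
exclude_arrays <- function(matrix, report, sheet = NULL) {
  if (!all(report$array_id %in% colnames(matrix)))
    ifl_stop("validation", "QC report refers to arrays absent from the matrix")
  drop <- report$array_id[report$flagged]
  keep <- setdiff(colnames(matrix), drop)
  out <- matrix[, keep, drop = FALSE]
  if (!is.null(sheet)) {
    surv <- sheet[sheet$array_id %in% keep, ]
    n <- table(factor(surv$treatment, levels = TREATMENTS))
    if (any(n < 2L))
      ifl_stop("design", "treatment(s) %s left with < 2 arrays after exclusion",
               paste(names(n)[n < 2], collapse = ", "))
    message(sprintf("arrays retained per treatment: %s",
                    paste(sprintf("%s=%d", names(n), n), collapse = ", ")))
  }
  attr(out, "log2") <- attr(matrix, "log2")
  out
}

#' Optional between-array quantile normalization
#'
#' Off by default in the pipeline (the upstream study reports none). Uses
#' limma's quantile normalization when requested.
#'
#' @param matrix Expression matrix.
#' @return Quantile-normalized matrix.
#' @export
normalize_arrays <- function(matrix) {
  if (!requireNamespace("limma", quietly = TRUE))
    ifl_stop("dependency", "quantile normalization requires the limma package")
  out <- limma::normalizeQuantiles(matrix)
  dimnames(out) <- dimnames(matrix)
  attr(out, "log2") <- attr(matrix, "log2")
  out
}
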