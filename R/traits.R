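# Correlation of cluster mean expression (or single genes) with
# individual-level traits, Bonferroni-controlled within each unit's family.

#' Pearson (or Spearman) correlation with a t-based p-value
#'
#' Uses pairwise deletion of missing values; the p-value comes from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom
#' (two-sided), with p = 0 at |r| = 1.
#'
#' @param x,y Numeric vectors of equal length.
#' @param method `"pearson"` (default) or `"spearman"` (ranks, same t
#'   approximation).
#' @return List with `r`, `p` and `n` (complete pairs used).
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- stats::complete.cases(x, y)
  n <- sum(ok)
  if (n < 3L)
    ifl_stop("insufficient_data", "need >= 3 complete pairs, got %d", n)
  x <- x[ok]; y <- y[ok]
  if (method == "spearman") { x <- rank(x); y <- rank(y) }
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    ifl_stop("undefined_correlation", "zero variance in x or y")
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t), n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Correlate expression units with traits
#'
#' Correlates each unit (cluster mean profile or single-gene row, one row of
#' `units` per unit with arrays as columns) against every trait column in the
#' trait table, aligning arrays to individuals through the sample sheet. A
#' correlation is significant when `p < alpha_corr_family / m`, where `m` is
#' the number of traits tested per unit (the Bonferroni family; with the
#' defaults 0.05 / 10 = 0.005).
#'
#' @param units Unit x array numeric matrix.
#' @param traits Trait table with `individual_id` plus trait columns.
#' @param sheet Sample sheet mapping arrays to individuals.
#' @param params [analysis_params()] (family-wise level `alpha_corr_family`).
#' @param method Correlation type passed to [correlate()].
#' @return Data frame per (unit, trait): `unit`, `trait`, `n`, `r`, `p`,
#'   `significant`; the per-comparison threshold is attached as attribute
#'   `threshold`.
#' @export
correlate_units <- function(units, traits, sheet, params = analysis_params(),
                            method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot_numeric_matrix(units, "units")
  ind <- sheet$individual_id[match(colnames(units), sheet$array_id)]
  if (anyNA(ind))
    ifl_stop("validation", "array(s) missing from sample sheet: %s",
             paste(colnames(units)[is.na(ind)], collapse = ", "))
  trait_cols <- setdiff(names(traits), "individual_id")
  if (!length(trait_cols)) ifl_stop("validation", "trait table has no trait columns")
  rowi <- match(ind, traits$individual_id)
  if (all(is.na(rowi)))
    ifl_stop("validation", "no overlapping individuals between arrays and traits")
  m <- length(trait_cols)
  threshold <- params$alpha_corr_family / m
  rows <- list()
  for (u in rownames(units)) {
    for (tr in trait_cols) {
      x <- units[u, ]
      y <- traits[[tr]][rowi]
      n_ok <- sum(stats::complete.cases(x, y))
      res <- if (n_ok >= 3L && n_ok > 0 &&
                 isTRUE(tryCatch(stats::sd(x[stats::complete.cases(x, y)]) > 0 &&
                                 stats::sd(y[stats::complete.cases(x, y)]) > 0,
                                 error = function(e) FALSE))) {
        correlate(x, y, method = method)
      } else list(r = NA_real_, p = NA_real_, n = n_ok)
      rows[[length(rows) + 1L]] <- data.frame(
        unit = u, trait = tr, n = res$n, r = res$r, p = res$p,
        significant = !is.na(res$p) && res$p < threshold,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- threshold
  attr(out, "m") <- m
  out
}
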