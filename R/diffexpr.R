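# Four-group linear model, empirical-Bayes variance moderation, pairwise
# moderated-t contrasts, Benjamini-Hochberg adjustment, and the joint
# significance / fold-change inclusion filter.
#
# Model: for gene g and treatment t, x ~ N(mu_gt, sigma_g^2) with a common
# within-group variance per gene. The gene-wise variances receive a scaled
# inverse-chi-square prior sigma_g^2 ~ s0^2 * d0 / chisq_d0, estimated from
# the data by method of moments on log sample variances; the posterior
# variance s~_g^2 = (d0 s0^2 + d s_g^2) / (d0 + d) feeds a t statistic with
# d + d0 degrees of freedom.

#' Analysis parameters
#'
#' @param alpha_de Significance level of the inclusion filter (default 0.01,
#'   applied to BH-adjusted p-values by default).
#' @param fc_min Minimum fold change on the natural scale (default 1.4;
#'   equivalently |log2 difference| >= log2(1.4) ~ 0.4854).
#' @param use_adjusted_p Apply `alpha_de` to BH-adjusted p-values (`TRUE`,
#'   default) or raw p-values.
#' @param moderation `"ebayes"` (default) or `"ordinary"` (no shrinkage).
#' @param k_clusters Number of gene clusters for the fixed-k cut (default 4).
#' @param alpha_corr_family Family-wise level for trait correlations
#'   (default 0.05).
#' @param m_corr Bonferroni family size per unit for trait correlations
#'   (default 10 = 7 physiological traits + 3 appetite genes).
#' @return An object of class `analysis_params`.
#' @export
analysis_params <- function(alpha_de = 0.01, fc_min = 1.4,
                            use_adjusted_p = TRUE,
                            moderation = c("ebayes", "ordinary"),
                            k_clusters = 4L,
                            alpha_corr_family = 0.05, m_corr = 10L) {
  moderation <- match.arg(moderation)
  if (alpha_de <= 0 || alpha_de >= 1)
    ifl_stop("configuration", "alpha_de must be in (0, 1)")
  if (fc_min <= 1) ifl_stop("configuration", "fc_min must exceed 1")
  if (m_corr < 1L) ifl_stop("configuration", "m_corr must be >= 1")
  structure(list(alpha_de = alpha_de, fc_min = fc_min,
                 use_adjusted_p = isTRUE(use_adjusted_p),
                 moderation = moderation, k_clusters = as.integer(k_clusters),
                 alpha_corr_family = alpha_corr_family,
                 m_corr = as.integer(m_corr)),
            class = "analysis_params")
}

#' Fit the per-gene four-group linear model
#'
#' Estimates within-group means and the pooled within-group residual variance
#' per gene, with `N - 4` residual degrees of freedom.
#'
#' @param matrix Probe-set x array log2 expression matrix.
#' @param sheet Sample sheet mapping arrays to treatments.
#' @return An object of class `group_fit`: list with `means` (genes x 4),
#'   `s2`, `df`, and per-treatment sizes `n`.
#' @export
fit_linear_model <- function(matrix, sheet) {
  stopifnot_numeric_matrix(matrix, "matrix")
  unlabeled <- setdiff(colnames(matrix), sheet$array_id)
  if (length(unlabeled))
    ifl_stop("validation", "array(s) missing from sample sheet: %s",
             paste(unlabeled, collapse = ", "))
  treat <- sheet$treatment[match(colnames(matrix), sheet$array_id)]
  n <- table(factor(treat, levels = TREATMENTS))
  if (any(n < 2L))
    ifl_stop("design", "treatment(s) %s have < 2 arrays",
             paste(names(n)[n < 2], collapse = ", "))
  means <- vapply(TREATMENTS,
                  function(t) rowMeans(matrix[, treat == t, drop = FALSE]),
                  numeric(nrow(matrix)))
  if (is.null(dim(means)))
    means <- matrix(means, 1L, dimnames = list(rownames(matrix), TREATMENTS))
  resid <- matrix - means[, treat, drop = FALSE]
  df <- ncol(matrix) - length(TREATMENTS)
  s2 <- rowSums(resid^2) / df
  structure(list(means = means, s2 = s2, df = df,
                 n = stats::setNames(as.integer(n), names(n)),
                 genes = rownames(matrix)),
            class = "group_fit")
}

# Solve trigamma(x) = y for x > 0 by monotone bisection (trigamma is
# strictly decreasing). Bracket by doubling, then bisect to tol.
trigamma_inverse <- function(y, tol = 1e-8) {
  lo <- 1e-6
  hi <- 1
  while (trigamma(hi) > y) hi <- hi * 2
  while (trigamma(lo) < y) lo <- lo / 2
  while (hi - lo > tol * max(1, lo)) {
    mid <- (lo + hi) / 2
    if (trigamma(mid) > y) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Estimate the empirical-Bayes variance prior
#'
#' Method of moments on `z = log(s^2)`: the excess of `var(z)` over
#' `trigamma(d/2)` identifies the prior degrees of freedom `d0` (via monotone
#' bisection of the trigamma function); the mean of `z`, corrected by
#' `log(d/2) - digamma(d/2)` for the chi-square log bias (and the matching
#' `d0` term when finite), identifies the prior scale `s0^2`. No excess
#' dispersion gives `d0 = Inf` (all posterior variances equal `s0^2`);
#' `moderation = "ordinary"` gives `d0 = 0` (no shrinkage).
#'
#' @param fit A [fit_linear_model()] result.
#' @param moderation `"ebayes"` or `"ordinary"`.
#' @return An object of class `variance_prior`: list with `d0` and `s0sq`.
#' @export
estimate_variance_prior <- function(fit, moderation = c("ebayes", "ordinary")) {
  moderation <- match.arg(moderation)
  if (!inherits(fit, "group_fit"))
    ifl_stop("validation", "fit must come from fit_linear_model()")
  if (moderation == "ordinary")
    return(structure(list(d0 = 0, s0sq = NA_real_), class = "variance_prior"))
  pos <- fit$s2 > 0
  if (!any(pos))
    ifl_stop("degenerate_data", "all gene variances are zero")
  if (sum(pos) < 100L) {
    warning("fewer than 100 genes with positive variance; falling back to ordinary (unmoderated) variances")
    return(structure(list(d0 = 0, s0sq = NA_real_), class = "variance_prior"))
  }
  d <- fit$df
  z <- log(fit$s2[pos])
  bias <- log(d / 2) - digamma(d / 2)  # E[log(chisq_d/d)] = -bias
  excess <- stats::var(z) - trigamma(d / 2)
  if (excess <= 0) {
    d0 <- Inf
    s0sq <- exp(mean(z) + bias)
  } else {
    d0 <- 2 * trigamma_inverse(excess)
    s0sq <- exp(mean(z) + bias - (log(d0 / 2) - digamma(d0 / 2)))
  }
  structure(list(d0 = d0, s0sq = s0sq), class = "variance_prior")
}

#' Posterior (moderated) gene variances
#'
#' @param fit A [fit_linear_model()] result.
#' @param prior A [estimate_variance_prior()] result.
#' @return Numeric vector of posterior variances
#'   `(d0 s0^2 + d s^2) / (d0 + d)`; the sample variances when `d0 = 0`, the
#'   prior scale when `d0 = Inf`.
#' @export
squeeze_variances <- function(fit, prior) {
  d0 <- prior$d0
  if (d0 == 0) return(fit$s2)
  if (!is.finite(d0)) return(rep(prior$s0sq, length(fit$s2)))
  (d0 * prior$s0sq + fit$df * fit$s2) / (d0 + fit$df)
}

#' All pairwise moderated-t contrasts
#'
#' For each of the six treatment pairs computes the mean log2 difference, the
#' moderated t statistic `delta / sqrt(s~^2 (1/nX + 1/nY))`, a two-sided
#' p-value from the t distribution with `d + d0` degrees of freedom (normal
#' when `d0 = Inf`), and BH-adjusted p-values within each pair's gene-wise
#' family.
#'
#' @param fit A [fit_linear_model()] result.
#' @param prior A [estimate_variance_prior()] result.
#' @return Long data frame (gene x pair) with columns `gene`, `pair`,
#'   `delta_log2`, `fold_change`, `t`, `p`, `p_adj`.
#' @export
pairwise_contrasts <- function(fit, prior) {
  st2 <- squeeze_variances(fit, prior)
  dft <- fit$df + prior$d0
  out <- lapply(contrast_pairs(), function(pr) {
    m <- pair_members(pr)
    delta <- fit$means[, m[1]] - fit$means[, m[2]]
    se <- sqrt(st2 * (1 / fit$n[[m[1]]] + 1 / fit$n[[m[2]]]))
    tstat <- ifelse(se > 0, delta / se, ifelse(delta == 0, 0, sign(delta) * Inf))
    p <- if (is.finite(dft)) 2 * stats::pt(-abs(tstat), dft)
         else 2 * stats::pnorm(-abs(tstat))
    data.frame(gene = fit$genes, pair = pr, delta_log2 = delta,
               fold_change = 2^abs(delta), t = tstat, p = p,
               p_adj = adjust_bh(p),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  res <- do.call(rbind, out)
  attr(res, "df_total") <- dft
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Adjusted p-values (FDR), in input order.
#' @export
adjust_bh <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1))
    ifl_stop("validation", "p-values must lie in [0, 1] with no missing values")
  stats::p.adjust(p, method = "BH")
}

#' Apply the joint inclusion filter to a contrast table
#'
#' A (gene, pair) row passes when its p-value (BH-adjusted by default) is
#' strictly below `alpha_de` and its fold change is at least `fc_min`, both in
#' that same pair.
#'
#' @param table A [pairwise_contrasts()] table.
#' @param params [analysis_params()].
#' @return The table with a logical `passes` column appended.
#' @export
flag_passes <- function(table, params) {
  pp <- if (params$use_adjusted_p) table$p_adj else table$p
  table$passes <- pp < params$alpha_de & table$fold_change >= params$fc_min
  table
}

#' Filter differentially expressed genes
#'
#' @param table A [pairwise_contrasts()] table.
#' @param params [analysis_params()].
#' @return Sorted character vector of genes passing the joint filter in at
#'   least one pair (the DEG set).
#' @export
filter_de <- function(table, params) {
  tab <- flag_passes(table, params)
  sort(unique(tab$gene[tab$passes]))
}

#' Up/down-regulation counts per pair and in union
#'
#' "Up" in pair `X-Y` means passing the filter with expression higher in `X`
#' (the first-named group). A gene up in one pair and down in another counts
#' once in each union.
#'
#' @param table A [pairwise_contrasts()] table.
#' @param params [analysis_params()].
#' @return List with `per_pair` (data frame pair/up/down) and scalar
#'   `union_up`, `union_down`.
#' @export
updown_counts <- function(table, params) {
  tab <- flag_passes(table, params)
  per_pair <- do.call(rbind, lapply(contrast_pairs(), function(pr) {
    s <- tab[tab$pair == pr & tab$passes, ]
    data.frame(pair = pr, up = sum(s$delta_log2 > 0), down = sum(s$delta_log2 < 0),
               stringsAsFactors = FALSE)
  }))
  up_genes <- unique(tab$gene[tab$passes & tab$delta_log2 > 0])
  down_genes <- unique(tab$gene[tab$passes & tab$delta_log2 < 0])
  list(per_pair = per_pair,
       union_up = length(up_genes), union_down = length(down_genes))
}
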