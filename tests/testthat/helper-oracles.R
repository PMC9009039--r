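# Independent oracles and small fixtures shared across tests. Oracles are
# deliberately naive (brute force / enumeration) and never reuse package code
# for the quantity they check.

# Brute-force Benjamini-Hochberg step-up: q_(i) = min_{j >= i} p_(j) * n / j.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(n)
  for (i in seq_len(n)) q[i] <- min(pmin(ps[i:n] * n / (i:n), 1))
  out <- numeric(n)
  out[o] <- q
  out
}

# Exhaustive hypergeometric upper tail P(X >= k) by enumerating all
# selections of size n from a universe of size N with K marked elements.
hyper_oracle <- function(N, K, n, k) {
  sel <- utils::combn(N, n)
  marked <- seq_len(K)
  hits <- apply(sel, 2, function(s) sum(s %in% marked))
  mean(hits >= k)
}

# Ordinary pooled-variance two-group t-test on group means from a fit.
ordinary_t_oracle <- function(fit, pair) {
  m <- strsplit(pair, "-", fixed = TRUE)[[1]]
  delta <- fit$means[, m[1]] - fit$means[, m[2]]
  se <- sqrt(fit$s2 * (1 / fit$n[[m[1]]] + 1 / fit$n[[m[2]]]))
  t <- ifelse(se > 0, delta / se, ifelse(delta == 0, 0, sign(delta) * Inf))
  list(t = t, p = 2 * stats::pt(-abs(t), fit$df))
}

# Literal per-gene re-derivation of the pattern flags from sig/dir triples,
# written as plain ifs (the implementation vectorizes).
pattern_oracle <- function(sig, dir, strict_requires_f2sk = TRUE) {
  s <- function(p) sig[[p]]
  d <- function(p) dir[[p]]
  chronic <- s("F2-AL") && s("SK-AL") && d("F2-AL") == d("SK-AL")
  strict <- s("F2-AL") && s("SK-AL") && d("F2-AL") != d("SK-AL") &&
    (!strict_requires_f2sk || s("F2-SK"))
  cdir <- if (!chronic) "none" else if (d("F2-AL") > 0) "up" else "down"
  list(
    switching_broad = s("F2-SK") && (s("F2-AL") || s("SK-AL")),
    switching_strict = strict,
    chronic = chronic,
    chronic_direction = cdir,
    chronic_and_switching = chronic && s("F2-SK"),
    chronic_pure = chronic && !s("F2-SK"),
    robust_chronic = chronic &&
      s("F2-CR") && d("F2-CR") == d("F2-AL") &&
      s("SK-CR") && d("SK-CR") == d("F2-AL"))
}

# Build a contrast table realizing given significance/direction settings:
# config is a list per gene of named sig (logical) and dir (+1/-1) vectors
# over the six pairs. Significant rows get p_adj well under 0.01 and
# |delta| = 0.6 (> log2 1.4); non-significant rows get p = 0.5.
make_contrast_table <- function(configs) {
  genes <- rep(names(configs), each = 6L)
  pairs <- rep(contrast_pairs(), times = length(configs))
  sig <- mapply(function(g, pr) isTRUE(configs[[g]]$sig[[pr]]), genes, pairs)
  dir <- mapply(function(g, pr) {
    d <- configs[[g]]$dir[[pr]]
    if (is.null(d)) 1 else d
  }, genes, pairs)
  delta <- dir * 0.6
  p <- ifelse(sig, 1e-4, 0.5)
  data.frame(gene = genes, pair = pairs, delta_log2 = delta,
             fold_change = 2^abs(delta), t = dir * ifelse(sig, 8, 0.5),
             p = p, p_adj = p, stringsAsFactors = FALSE, row.names = NULL)
}

# Small simulated dataset summarized to the gene level, with fit/prior/table.
run_small_pipeline <- function(config) {
  sim <- simulate_dataset(config)
  expr <- summarize_probesets(sim$probe_matrix, sim$probe_map)
  fit <- fit_linear_model(expr, sim$sample_sheet)
  prior <- estimate_variance_prior(fit)
  table <- pairwise_contrasts(fit, prior)
  list(sim = sim, expr = expr, fit = fit, prior = prior, table = table)
}

# Adjusted Rand index (via mclust when available).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
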