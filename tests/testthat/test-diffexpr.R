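make_sheet <- function(n = c(AL = 2, CR = 2, F2 = 2, SK = 2)) {
  treat <- rep(names(n), n)
  data.frame(array_id = sprintf("A%02d", seq_along(treat)), treatment = treat,
             individual_id = sprintf("i%02d", seq_along(treat)),
             stringsAsFactors = FALSE)
}

test_that("group fit matches hand-computed means and pooled variance", {
  sheet <- make_sheet()
  m <- matrix(c(1, 3, 2, 4, 0, 0, 0, 0), nrow = 1,
              dimnames = list("g1", sheet$array_id))
  fit <- fit_linear_model(m, sheet)
  expect_equal(unname(fit$means["g1", ]), c(2, 3, 0, 0))
  expect_equal(fit$df, 4L)
  expect_equal(unname(fit$s2), 1)  # SS = 2 + 2 + 0 + 0 over d = 4

  m2 <- matrix(5, 1, 8, dimnames = list("g1", sheet$array_id))
  fit2 <- fit_linear_model(m2, sheet)
  expect_true(all(fit2$means == 5))
  expect_equal(unname(fit2$s2), 0)

  sheet_bad <- sheet[-(1:1), ]
  expect_error(fit_linear_model(m[, -1, drop = FALSE], sheet_bad),
               class = "ifliver_design")
})

test_that("variance-prior estimation recovers generating parameters", {
  cfg <- sim_config(n_probesets = 5000L, class_proportions = c(null = 1), seed = 21L)
  res <- run_small_pipeline(cfg)
  expect_gte(res$prior$d0, 2.5)
  expect_lte(res$prior$d0, 7)
  expect_lt(abs(res$prior$s0sq - 0.05) / 0.05, 0.2)
})

test_that("prior degenerate modes: no dispersion, ordinary, all-zero", {
  sheet <- make_sheet(c(AL = 3, CR = 3, F2 = 3, SK = 3))
  set.seed(1)
  # equal gene variances up to chi-square sampling: construct exactly equal s2
  m <- matrix(rnorm(200 * 12, 8, 1), 200, 12,
              dimnames = list(sprintf("g%03d", 1:200), sheet$array_id))
  fit <- fit_linear_model(m, sheet)
  fit$s2 <- rep(0.04, 200)  # identical sample variances
  prior <- estimate_variance_prior(fit)
  expect_identical(prior$d0, Inf)
  # MoM log-scale correction: s0^2 = s2 * exp(log(d/2) - digamma(d/2))
  d <- fit$df
  expect_equal(prior$s0sq, 0.04 * exp(log(d / 2) - digamma(d / 2)), tolerance = 1e-12)
  expect_equal(squeeze_variances(fit, prior), rep(prior$s0sq, 200))

  ord <- estimate_variance_prior(fit, moderation = "ordinary")
  expect_identical(ord$d0, 0)
  expect_identical(squeeze_variances(fit, ord), fit$s2)

  fit$s2 <- rep(0, 200)
  expect_error(estimate_variance_prior(fit), class = "ifliver_degenerate_data")
})

test_that("prior estimation agrees with limma's fitFDist", {
  skip_if_not_installed("limma")
  cfg <- sim_config(n_probesets = 2000L, class_proportions = c(null = 1), seed = 22L)
  res <- run_small_pipeline(cfg)
  ref <- limma::fitFDist(res$fit$s2, df1 = res$fit$df)
  expect_equal(res$prior$d0, ref$df2, tolerance = 1e-4)
  expect_equal(res$prior$s0sq, ref$scale, tolerance = 1e-6)
})

test_that("moderated contrasts agree with limma on a simulated dataset", {
  skip_if_not_installed("limma")
  cfg <- sim_config(n_probesets = 500L, seed = 23L)
  res <- run_small_pipeline(cfg)
  treat <- res$sim$sample_sheet$treatment
  design <- stats::model.matrix(~ 0 + factor(treat, levels = c("AL", "CR", "F2", "SK")))
  colnames(design) <- c("AL", "CR", "F2", "SK")
  fit <- limma::lmFit(res$expr, design)
  cm <- limma::makeContrasts(F2 - AL, SK - AL, CR - AL, F2 - SK, F2 - CR, SK - CR,
                             levels = design)
  eb <- limma::eBayes(limma::contrasts.fit(fit, cm))
  for (j in seq_along(contrast_pairs())) {
    ours <- res$table[res$table$pair == contrast_pairs()[j], ]
    expect_equal(ours$t, unname(eb$t[ours$gene, j]), tolerance = 1e-6)
    expect_equal(ours$p, unname(eb$p.value[ours$gene, j]), tolerance = 1e-6)
  }
})

test_that("hand-computed moderated t: two groups n = 3, means 1 and 0, s~2 = 0.25", {
  t_expect <- 1 / sqrt(0.25 * (2 / 3))
  expect_equal(t_expect, 2.449, tolerance = 1e-3)
  sheet <- make_sheet(c(AL = 3, CR = 3, F2 = 3, SK = 3))
  fit <- structure(list(means = matrix(c(0, 0, 1, 0), 1,
                                       dimnames = list("g1", c("AL", "CR", "F2", "SK"))),
                        s2 = c(g1 = 0.25), df = 8L,
                        n = c(AL = 3L, CR = 3L, F2 = 3L, SK = 3L), genes = "g1"),
                   class = "group_fit")
  prior <- structure(list(d0 = 10, s0sq = 0.25), class = "variance_prior")
  tab <- pairwise_contrasts(fit, prior)  # s~2 stays 0.25, df = 18
  row <- tab[tab$pair == "F2-AL", ]
  expect_equal(row$t, t_expect, tolerance = 1e-12)
  expect_equal(row$p, 2 * pt(-abs(t_expect), 18), tolerance = 1e-12)

  # equal means give t = 0, p = 1
  row0 <- tab[tab$pair == "CR-AL", ]
  expect_equal(row0$t, 0)
  expect_equal(row0$p, 1)
})

test_that("pair orientation: t antisymmetric, p invariant", {
  cfg <- sim_config(n_probesets = 100L, seed = 24L)
  res <- run_small_pipeline(cfg)
  # recompute the reversed pair by hand from the fit
  st2 <- squeeze_variances(res$fit, res$prior)
  delta_rev <- res$fit$means[, "AL"] - res$fit$means[, "F2"]
  se <- sqrt(st2 * (1 / 6 + 1 / 4))
  t_rev <- delta_rev / se
  ours <- res$table[res$table$pair == "F2-AL", ]
  expect_equal(ours$t, -unname(t_rev[ours$gene]), tolerance = 1e-12)
  p_rev <- 2 * pt(-abs(t_rev), res$fit$df + res$prior$d0)
  expect_equal(ours$p, unname(p_rev[ours$gene]), tolerance = 1e-12)
})

test_that("with d0 = 0 the moderated t reduces exactly to the ordinary pooled t", {
  for (seed in 1:5) {
    cfg <- sim_config(n_probesets = 50L, seed = seed)
    sim <- simulate_dataset(cfg)
    expr <- summarize_probesets(sim$probe_matrix, sim$probe_map)
    fit <- fit_linear_model(expr, sim$sample_sheet)
    tab <- pairwise_contrasts(fit, estimate_variance_prior(fit, "ordinary"))
    for (pr in contrast_pairs()) {
      oracle <- ordinary_t_oracle(fit, pr)
      ours <- tab[tab$pair == pr, ]
      expect_identical(ours$t, unname(oracle$t[ours$gene]))
      expect_identical(ours$p, unname(oracle$p[ours$gene]))
    }
  }
})

test_that("BH adjustment equals the brute-force step-up oracle", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_equal(adjust_bh(0.37), 0.37)
  expect_error(adjust_bh(c(0.5, 1.2)), class = "ifliver_validation")
  expect_error(adjust_bh(c(0.5, NA)), class = "ifliver_validation")
  set.seed(3)
  for (i in 1:25) {
    p <- round(runif(sample(1:200, 1)), sample(1:3, 1))  # ties included
    expect_lt(max(abs(adjust_bh(p) - bh_oracle(p))), 1e-12)
  }
})

test_that("the inclusion filter applies p and fold change jointly per pair", {
  params <- analysis_params()
  cfgs <- list(
    in_one_pair = list(sig = stats::setNames(as.list(c(TRUE, rep(FALSE, 5))), contrast_pairs())),
    never = list(sig = stats::setNames(as.list(rep(FALSE, 6)), contrast_pairs())))
  tab <- make_contrast_table(cfgs)
  # shrink one gene's deltas below the fold-change bar but keep p tiny
  small <- tab$gene == "never"
  tab$p[small] <- 0.005; tab$p_adj[small] <- 0.005
  tab$delta_log2[small] <- 0.3; tab$fold_change[small] <- 2^0.3
  expect_identical(filter_de(tab, params), "in_one_pair")
  # |delta| >= log2(1.4) is the fold-change criterion on the log scale
  expect_equal(log2(1.4), 0.4854, tolerance = 1e-4)
})

test_that("DE monotonicity: growing |delta| at fixed variance never drops a gene", {
  params <- analysis_params(use_adjusted_p = FALSE)
  fit <- structure(list(means = matrix(c(0, 0, 0.6, 0), 1,
                                       dimnames = list("g1", c("AL", "CR", "F2", "SK"))),
                        s2 = c(g1 = 0.2), df = 18L,
                        n = c(AL = 6L, CR = 6L, F2 = 4L, SK = 6L), genes = "g1"),
                   class = "group_fit")
  prior <- structure(list(d0 = 0, s0sq = NA_real_), class = "variance_prior")
  included <- logical(0)
  for (delta in seq(0.5, 2, by = 0.25)) {
    fit$means[1, "F2"] <- delta
    included <- c(included, length(filter_de(pairwise_contrasts(fit, prior), params)) == 1L)
  }
  expect_true(all(diff(included) >= 0))
  expect_true(included[length(included)])
})

test_that("statistics are invariant to permuting arrays within treatments", {
  cfg <- sim_config(n_probesets = 100L, seed = 25L)
  sim <- simulate_dataset(cfg)
  expr <- summarize_probesets(sim$probe_matrix, sim$probe_map)
  sheet <- sim$sample_sheet
  fit1 <- fit_linear_model(expr, sheet)
  # permute columns within each treatment block
  perm <- unlist(lapply(split(seq_len(nrow(sheet)), sheet$treatment),
                        function(i) sample(i)), use.names = FALSE)
  expr2 <- expr[, perm]
  fit2 <- fit_linear_model(expr2, sheet)
  expect_equal(fit1$means, fit2$means, tolerance = 1e-12)
  expect_equal(fit1$s2, fit2$s2, tolerance = 1e-12)
})

test_that("up/down counts honour direction and unions", {
  params <- analysis_params()
  cfgs <- list(
    up_then_down = list(sig = stats::setNames(as.list(c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)),
                                              contrast_pairs()),
                        dir = stats::setNames(as.list(c(1, -1, 1, 1, 1, 1)), contrast_pairs())))
  tab <- make_contrast_table(cfgs)
  ud <- updown_counts(tab, params)
  expect_equal(ud$per_pair$up[ud$per_pair$pair == "F2-AL"], 1L)
  expect_equal(ud$per_pair$down[ud$per_pair$pair == "SK-AL"], 1L)
  expect_equal(ud$union_up, 1L)
  expect_equal(ud$union_down, 1L)  # same gene counted once in each union

  empty <- make_contrast_table(list(g = list(sig = stats::setNames(as.list(rep(FALSE, 6)),
                                                                   contrast_pairs()))))
  ud0 <- updown_counts(empty, params)
  expect_true(all(ud0$per_pair$up == 0) && all(ud0$per_pair$down == 0))
})
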