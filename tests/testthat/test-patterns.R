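pairs6 <- contrast_pairs()

test_that("definition cases: strict switching, pure chronic, chronic-and-switching", {
  params <- analysis_params()
  cfgs <- list(
    strict = list(sig = stats::setNames(as.list(c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)), pairs6),
                  dir = stats::setNames(as.list(c(1, -1, 1, 1, 1, -1)), pairs6)),
    chronic_pure = list(sig = stats::setNames(as.list(c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)), pairs6),
                        dir = stats::setNames(as.list(rep(1, 6)), pairs6)),
    chronic_switch_robust = list(sig = stats::setNames(as.list(c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)), pairs6),
                                 dir = stats::setNames(as.list(rep(1, 6)), pairs6)))
  calls <- classify_gene_patterns(make_contrast_table(cfgs), params)
  rownames(calls) <- calls$gene

  expect_true(calls["strict", "switching_strict"])
  expect_false(calls["strict", "chronic"])
  expect_true(calls["strict", "switching_broad"])

  expect_true(calls["chronic_pure", "chronic"])
  expect_true(calls["chronic_pure", "chronic_pure"])
  expect_false(calls["chronic_pure", "chronic_and_switching"])
  expect_equal(calls["chronic_pure", "chronic_direction"], "up")
  expect_false(calls["chronic_pure", "robust_chronic"])

  expect_true(calls["chronic_switch_robust", "chronic_and_switching"])
  expect_true(calls["chronic_switch_robust", "robust_chronic"])
  expect_false(calls["chronic_switch_robust", "switching_strict"])
})

test_that("flag logic equals the truth-table oracle over all 3^6 configurations", {
  params <- analysis_params()
  states <- expand.grid(rep(list(c("ns", "up", "down")), 6), stringsAsFactors = FALSE)
  names(states) <- pairs6
  cfgs <- lapply(seq_len(nrow(states)), function(i) {
    st <- unlist(states[i, ])
    list(sig = as.list(stats::setNames(st != "ns", pairs6)),
         dir = as.list(stats::setNames(ifelse(st == "down", -1, 1), pairs6)))
  })
  names(cfgs) <- sprintf("g%03d", seq_along(cfgs))
  calls <- classify_gene_patterns(make_contrast_table(cfgs), params)
  oracle <- lapply(cfgs, function(cf) pattern_oracle(cf$sig, cf$dir))
  oracle_df <- do.call(rbind, lapply(oracle, function(o)
    as.data.frame(o, stringsAsFactors = FALSE)))
  idx <- match(names(cfgs), calls$gene)
  for (fl in c("switching_broad", "switching_strict", "chronic",
               "chronic_and_switching", "chronic_pure", "robust_chronic"))
    expect_identical(calls[[fl]][idx], unname(oracle_df[[fl]]),
                     label = fl)
  expect_identical(calls$chronic_direction[idx], unname(oracle_df$chronic_direction))
  # structural exclusions, verified exhaustively
  expect_false(any(calls$switching_strict & calls$chronic))
  expect_false(any(calls$chronic_and_switching & calls$chronic_pure))
  expect_true(all(calls$chronic_and_switching + calls$chronic_pure == calls$chronic))
})

test_that("calls are stable under gene and pair-row reordering", {
  params <- analysis_params()
  set.seed(4)
  cfgs <- lapply(1:20, function(i) {
    list(sig = as.list(stats::setNames(sample(c(TRUE, FALSE), 6, TRUE), pairs6)),
         dir = as.list(stats::setNames(sample(c(-1, 1), 6, TRUE), pairs6)))
  })
  names(cfgs) <- sprintf("g%02d", 1:20)
  tab <- make_contrast_table(cfgs)
  ref <- classify_gene_patterns(tab, params)
  shuffled <- tab[sample(nrow(tab)), ]
  out <- classify_gene_patterns(shuffled, params)
  out <- out[match(ref$gene, out$gene), ]
  rownames(out) <- NULL
  expect_equal(out, ref)
})

test_that("missing pairs are rejected", {
  cfgs <- list(g1 = list(sig = stats::setNames(as.list(rep(TRUE, 6)), pairs6)))
  tab <- make_contrast_table(cfgs)
  expect_error(classify_gene_patterns(tab[-1, ], analysis_params()),
               class = "ifliver_validation")
})

test_that("probe-set calls collapse to gene level with discordance handling", {
  params <- analysis_params()
  up <- list(sig = stats::setNames(as.list(c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)), pairs6),
             dir = stats::setNames(as.list(rep(1, 6)), pairs6))
  down <- list(sig = up$sig, dir = stats::setNames(as.list(rep(-1, 6)), pairs6))
  calls <- classify_gene_patterns(make_contrast_table(list(ps1 = up, ps2 = up, ps3 = down,
                                                           ps4 = up, ps5 = down)),
                                  params)
  # identity map: unchanged calls, no duplicates
  id <- dedupe_to_genes(calls)
  expect_equal(nrow(id$calls), 5L)
  expect_equal(nrow(id$duplicates), 0L)

  map <- c(ps1 = "GENE_A", ps2 = "GENE_A", ps3 = "GENE_B", ps4 = "GENE_C", ps5 = "GENE_C")
  dd <- dedupe_to_genes(calls, map)
  g <- dd$calls
  rownames(g) <- g$gene
  expect_equal(nrow(g), 3L)
  expect_true(g["GENE_A", "chronic"])
  expect_equal(g["GENE_A", "chronic_direction"], "up")
  expect_false(g["GENE_A", "discordant"])
  # opposite directions collapse to a discordant gene with no direction
  expect_true(g["GENE_C", "discordant"])
  expect_equal(g["GENE_C", "chronic_direction"], "none")
  expect_setequal(dd$duplicates$symbol, c("GENE_A", "GENE_C"))
})

test_that("pattern summaries are exact set algebra", {
  params <- analysis_params()
  strict <- list(sig = stats::setNames(as.list(c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)), pairs6),
                 dir = stats::setNames(as.list(c(1, -1, 1, 1, 1, -1)), pairs6))
  chronic <- list(sig = stats::setNames(as.list(c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)), pairs6),
                  dir = stats::setNames(as.list(rep(-1, 6)), pairs6))
  none <- list(sig = stats::setNames(as.list(rep(FALSE, 6)), pairs6))
  calls <- classify_gene_patterns(
    make_contrast_table(list(a = strict, b = strict, c = strict,
                             d = chronic, e = chronic, f = none)), params)
  s <- summarize_patterns(calls)
  expect_equal(unname(s$counts["switching_strict"]), 3L)
  expect_equal(unname(s$counts["chronic"]), 2L)
  expect_equal(unname(s$counts["chronic_down"]), 2L)
  expect_equal(unname(s$counts["strict_also_chronic"]), 0L)
  expect_equal(sum(s$venn), 6L)

  empty <- calls[0, ]
  s0 <- summarize_patterns(empty)
  expect_true(all(s0$counts == 0L))
})

test_that("planted chronic and switching classes are recalled from simulations", {
  # moderate-size check across seeds; the full 20-seed recovery run lives in
  # the acceptance suite
  sens_num <- sens_den <- 0
  null_calls <- null_genes <- 0
  for (seed in 41:43) {
    res <- run_small_pipeline(sim_config(seed = seed))
    calls <- classify_gene_patterns(res$table, analysis_params())
    truth <- res$sim$truth
    chronic_true <- truth$gene_id[truth$class %in%
      c("chronic_up", "chronic_down", "chronic_and_switching_up")]
    idx <- match(chronic_true, calls$gene)
    sens_num <- sens_num + sum(calls$chronic[idx])
    sens_den <- sens_den + length(idx)
    nulls <- truth$gene_id[truth$class == "null"]
    null_calls <- null_calls + sum(calls$chronic[match(nulls, calls$gene)])
    null_genes <- null_genes + length(nulls)
  }
  expect_gt(sens_num / sens_den, 0.5)      # most planted chronics are called
  expect_lt(null_calls / null_genes, 0.01) # null chronic rate under the alpha bound
})
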