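# Ground-truth recovery evaluation: run the analysis stages on a synthetic
# dataset and score the results against the planted truth. This is the
# package's own validation harness; every quantity is recomputed from scratch
# for the given configuration.

#' Evaluate planted-truth recovery on a synthetic dataset
#'
#' Simulates a dataset, runs summarization, the moderated-t contrasts, the
#' inclusion filter, the pattern taxonomy and (optionally) the clustering
#' stage, and scores everything against the generating truth: DE-filter
#' sensitivity on non-null genes and inclusion rate on null genes, sensitivity
#' and precision of the chronic and strict-switching calls, the recovered
#' variance-prior parameters, the adjusted Rand index of the k = 4 gene-cluster
#' cut against the planted four-way archetype grouping, and whether the k = 2
#' sample cut separates the fed (AL, F2) from the underfed (CR, SK) states.
#'
#' @param config A [sim_config()].
#' @param params [analysis_params()].
#' @param do_cluster Run the clustering stage (default `TRUE`).
#' @return Named list of recovery statistics, plus the raw counts used.
#' @export
evaluate_recovery <- function(config, params = analysis_params(),
                              do_cluster = TRUE) {
  sim <- simulate_dataset(config)
  expr <- summarize_probesets(sim$probe_matrix, sim$probe_map)
  fit <- fit_linear_model(expr, sim$sample_sheet)
  prior <- estimate_variance_prior(fit, moderation = params$moderation)
  table <- pairwise_contrasts(fit, prior)
  deg <- filter_de(table, params)
  truth <- sim$truth

  nonnull <- truth$gene_id[truth$class != "null"]
  nulls <- truth$gene_id[truth$class == "null"]
  chronic_true <- truth$gene_id[truth$class %in%
    c("chronic_up", "chronic_down", "chronic_and_switching_up")]
  switching_true <- truth$gene_id[truth$class %in%
    c("switching_up_in_fast", "switching_down_in_fast")]

  calls <- classify_gene_patterns(table, params)
  chronic_called <- calls$gene[calls$chronic]
  switching_called <- calls$gene[calls$switching_strict]

  out <- list(
    n_filtered = length(deg),
    n_nonnull = length(nonnull),
    n_null = length(nulls),
    de_tp = length(intersect(deg, nonnull)),
    de_fp = length(intersect(deg, nulls)),
    chronic_tp = length(intersect(chronic_called, chronic_true)),
    chronic_called = length(chronic_called),
    chronic_true = length(chronic_true),
    switching_tp = length(intersect(switching_called, switching_true)),
    switching_called = length(switching_called),
    switching_true = length(switching_true),
    prior_d0 = prior$d0,
    prior_s0sq = prior$s0sq)
  out$de_sensitivity <- out$de_tp / out$n_nonnull
  out$de_null_inclusion <- out$de_fp / out$n_null
  out$chronic_sensitivity <- out$chronic_tp / max(1L, out$chronic_true)
  out$chronic_precision <- out$chronic_tp / max(1L, out$chronic_called)
  out$switching_sensitivity <- out$switching_tp / max(1L, out$switching_true)
  out$switching_precision <- out$switching_tp / max(1L, out$switching_called)

  if (do_cluster && length(deg) >= params$k_clusters) {
    std <- standardize_rows(expr[deg, , drop = FALSE])
    cut4 <- cut_k(cluster_genes(std), params$k_clusters)
    grp <- planted_four_groups(truth)[deg]
    keep <- !is.na(grp)
    out$cluster_ari <- adjusted_rand(cut4[keep], grp[keep])
    cut2 <- cut_k(cluster_samples(std), 2L)
    treat <- sim$sample_sheet$treatment[match(names(cut2), sim$sample_sheet$array_id)]
    fed <- treat %in% c("AL", "F2")
    out$sample_split_ok <- length(unique(cut2[fed])) == 1L &&
      length(unique(cut2[!fed])) == 1L && cut2[fed][1] != cut2[!fed][1]
  }
  out
}

#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie adjusted Rand index, computed from the contingency table of
#' the two labelings.
#'
#' @param a,b Equal-length label vectors.
#' @return The adjusted Rand index (1 for identical partitions).
#' @export
adjusted_rand <- function(a, b) {
  if (length(a) != length(b))
    ifl_stop("validation", "partitions must have equal length")
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
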