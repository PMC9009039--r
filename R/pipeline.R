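# End-to-end orchestration: simulate/ingest -> preprocess -> DE filter ->
# (cluster + enrichment + traits | patterns) with deterministic artifacts and
# a machine-readable run report.

#' Pipeline configuration
#'
#' Builds a validated pipeline configuration, either for a synthetic run
#' (supply `sim`) or a real-data run (supply the input paths). Stage toggles
#' control the two independent downstream branches; enrichment and trait
#' correlation run only when their inputs (`gmt`, `traits`) are available.
#'
#' @param out_dir Output directory for all written artifacts.
#' @param sim Optional [sim_config()] for synthetic runs.
#' @param expression,probe_map,samples,traits,gmt Optional input file paths
#'   for real-data runs (probe-level expression TSV, probe map TSV, sample
#'   sheet TSV, trait table TSV, pathway GMT).
#' @param params [analysis_params()].
#' @param log_scale Whether a real expression table is already log2.
#' @param normalize Apply between-array quantile normalization (default
#'   `FALSE`; the reference analysis reports none).
#' @param qc_min_corr,qc_pc_mad QC thresholds, see [flag_failed_arrays()].
#' @param stages Named logical list enabling stages: `qc`, `cluster`,
#'   `patterns`, `enrichment`, `traits`.
#' @param seed Integer seed (mandatory for synthetic runs).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            sim = NULL,
                            expression = NULL, probe_map = NULL,
                            samples = NULL, traits = NULL, gmt = NULL,
                            params = analysis_params(),
                            log_scale = TRUE,
                            normalize = FALSE,
                            qc_min_corr = 0.8, qc_pc_mad = 5,
                            stages = list(),
                            seed = NULL) {
  synthetic <- !is.null(sim)
  if (!synthetic && (is.null(expression) || is.null(probe_map) || is.null(samples)))
    ifl_stop("configuration",
             "either a sim config or expression + probe_map + samples paths are required")
  if (synthetic && is.null(seed)) seed <- sim$seed
  if (synthetic && is.null(seed))
    ifl_stop("configuration", "seed is mandatory for synthetic runs")
  st <- list(qc = TRUE, cluster = TRUE, patterns = TRUE,
             enrichment = TRUE, traits = TRUE)
  st[names(stages)] <- lapply(stages, isTRUE)
  structure(list(out_dir = out_dir, sim = sim, expression = expression,
                 probe_map = probe_map, samples = samples, traits = traits,
                 gmt = gmt, params = params, log_scale = log_scale,
                 normalize = normalize,
                 qc_min_corr = qc_min_corr, qc_pc_mad = qc_pc_mad,
                 stages = st, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors [pipeline_config()]: top-level keys `out_dir`, input
#' paths, `seed`, `stages`, plus optional `params` and `sim` blocks whose
#' entries are passed to [analysis_params()] and [sim_config()].
#'
#' @param path YAML file.
#' @return Object of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  params <- do.call(analysis_params, as.list(y$params))
  sim <- if (!is.null(y$sim)) {
    args <- as.list(y$sim)
    for (nm in c("n_per_treatment", "probes_per_set_weights", "class_proportions"))
      if (!is.null(args[[nm]])) args[[nm]] <- unlist(args[[nm]])
    do.call(sim_config, args)
  }
  pipeline_config(out_dir = y$out_dir, sim = sim,
                  expression = y$expression, probe_map = y$probe_map,
                  samples = y$samples, traits = y$traits, gmt = y$gmt,
                  params = params,
                  log_scale = if (is.null(y$log_scale)) TRUE else isTRUE(y$log_scale),
                  normalize = isTRUE(y$normalize),
                  qc_min_corr = if (is.null(y$qc_min_corr)) 0.8 else y$qc_min_corr,
                  qc_pc_mad = if (is.null(y$qc_pc_mad)) 5 else y$qc_pc_mad,
                  stages = if (is.null(y$stages)) list() else y$stages,
                  seed = y$seed)
}

run_stage <- function(report, name, expr) {
  res <- tryCatch(expr, error = function(e) {
    stop(errorCondition(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                        class = c("ifliver_stage_error", "ifliver_error")))
  })
  res
}

#' Run the full pipeline
#'
#' Executes the stages in dependency order: ingest or simulate, array QC and
#' exclusion, probe-set summarization, differential expression with the
#' inclusion filter, then two independent branches off the filtered set —
#' clustering (with optional enrichment and trait correlation) and pattern
#' classification. All artifacts are written as TSV/JSON under
#' `config$out_dir`; identical configurations produce byte-identical
#' artifacts.
#'
#' @param config A [pipeline_config()].
#' @return The run report (named list of per-stage row counts, parameters and
#'   headline counts), invisibly also written as `report.json`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    ifl_stop("configuration", "config must come from pipeline_config()")
  out_dir <- config$out_dir
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    ifl_stop("io", "cannot create output directory %s", out_dir)
  params <- config$params
  report <- list(parameters = unclass(params), stages = list())

  # ingest or simulate -------------------------------------------------------
  truth <- NULL
  traits_tab <- NULL
  if (!is.null(config$sim)) {
    sim <- run_stage(report, "simulate", simulate_dataset(config$sim))
    probes <- sim$probe_matrix
    map <- sim$probe_map
    sheet <- sim$sample_sheet
    truth <- sim$truth
    write_expression_table(probes, file.path(out_dir, "probe_matrix.tsv"))
    write_probe_map(map, file.path(out_dir, "probe_map.tsv"))
    write_sample_sheet(sheet, file.path(out_dir, "sample_sheet.tsv"))
    write_truth(truth, file.path(out_dir, "truth.tsv"))
  } else {
    probes <- run_stage(report, "ingest",
                        read_expression_table(config$expression, config$log_scale))
    map <- read_probe_map(config$probe_map)
    sheet <- read_sample_sheet(config$samples)
  }
  if (!is.null(config$traits)) {
    traits_tab <- if (is.character(config$traits)) read_trait_table(config$traits)
                  else config$traits
  }
  probes <- log_transform(probes, already_log = isTRUE(attr(probes, "log2")))
  report$stages$ingest <- list(n_probes = nrow(probes), n_arrays = ncol(probes))

  # QC and exclusion (before summarization; order is irrelevant for
  # per-array statistics) ----------------------------------------------------
  if (isTRUE(config$stages$qc)) {
    qc <- run_stage(report, "qc", {
      r <- array_qc_stats(probes)
      flag_failed_arrays(r, config$qc_min_corr, config$qc_pc_mad, sheet)
    })
    probes <- exclude_arrays(probes, qc, sheet)
    sheet <- sheet[sheet$array_id %in% colnames(probes), ]
    write_results(list(qc_report = qc), out_dir)
    report$stages$qc <- list(n_flagged = sum(qc$flagged),
                             flagged = qc$array_id[qc$flagged],
                             n_arrays_retained = ncol(probes))
  }
  if (isTRUE(config$normalize)) probes <- normalize_arrays(probes)

  expr <- run_stage(report, "summarize", summarize_probesets(probes, map))
  report$stages$summarize <- list(n_probesets = nrow(expr))

  # differential expression --------------------------------------------------
  de <- run_stage(report, "diffexpr", {
    fit <- fit_linear_model(expr, sheet)
    prior <- estimate_variance_prior(fit, moderation = params$moderation)
    tab <- flag_passes(pairwise_contrasts(fit, prior), params)
    list(fit = fit, prior = prior, table = tab)
  })
  deg <- filter_de(de$table, params)
  ud <- updown_counts(de$table, params)
  write_results(list(contrasts = de$table,
                     deg = data.frame(gene = deg, stringsAsFactors = FALSE),
                     updown = ud$per_pair),
                out_dir)
  report$stages$diffexpr <- list(
    d0 = de$prior$d0, s0sq = de$prior$s0sq,
    n_filtered = length(deg),
    union_up = ud$union_up, union_down = ud$union_down)

  bundle <- list()
  headline <- list(n_filtered = length(deg))

  # branch A: clustering, enrichment, traits ---------------------------------
  if (isTRUE(config$stages$cluster) && length(deg) >= params$k_clusters) {
    clus <- run_stage(report, "cluster", {
      std <- standardize_rows(expr[deg, , drop = FALSE])
      gd <- cluster_genes(std)
      assignment <- cut_k(gd, params$k_clusters)
      sd_ <- cluster_samples(std)
      cm <- cluster_means(std, assignment)
      list(std = std, assignment = assignment, sample_dend = sd_, means = cm)
    })
    leaf_order <- cluster_genes(clus$std)$order
    bundle$clusters <- data.frame(gene = names(clus$assignment),
                                  cluster = as.integer(clus$assignment),
                                  stringsAsFactors = FALSE)
    write_expression_table(clus$std[leaf_order, , drop = FALSE],
                           file.path(out_dir, "heatmap_matrix.tsv"),
                           id_column = "gene")
    cm_df <- data.frame(cluster = rownames(clus$means), clus$means,
                        check.names = FALSE, stringsAsFactors = FALSE)
    bundle$cluster_means <- cm_df
    headline$cluster_sizes <- as.integer(table(clus$assignment))
    report$stages$cluster <- list(k = params$k_clusters,
                                  sizes = headline$cluster_sizes)

    if (isTRUE(config$stages$enrichment) && !is.null(config$gmt)) {
      pathways <- if (is.character(config$gmt)) read_gmt(config$gmt) else config$gmt
      enr <- run_stage(report, "enrichment", {
        universe <- intersect(rownames(expr),
                              unique(unlist(lapply(pathways, `[[`, "genes"))))
        per_cluster <- lapply(sort(unique(clus$assignment)), function(k) {
          genes_k <- names(clus$assignment)[clus$assignment == k]
          tab <- ora(genes_k, pathways, universe)
          tab$cluster <- k
          su <- shared_unique(tab)
          cov <- coverage_stats(genes_k, pathways, tab)
          list(table = tab, shared_unique = su, coverage = cov)
        })
        per_cluster
      })
      bundle$enrichment <- do.call(rbind, lapply(enr, `[[`, "table"))
      su_all <- do.call(rbind, lapply(seq_along(enr), function(i) {
        su <- enr[[i]]$shared_unique
        if (nrow(su)) su$cluster <- i
        su
      }))
      if (!is.null(su_all) && nrow(su_all)) bundle$shared_unique <- su_all
      report$stages$enrichment <- list(
        n_pathways = length(pathways),
        coverage = lapply(enr, `[[`, "coverage"))
    }

    if (isTRUE(config$stages$traits) && !is.null(traits_tab)) {
      corr <- run_stage(report, "traits",
                        correlate_units(clus$means, traits_tab, sheet, params))
      bundle$correlations <- corr
      headline$n_significant_correlations <- sum(corr$significant)
      report$stages$traits <- list(threshold = attr(corr, "threshold"),
                                   m = attr(corr, "m"),
                                   n_significant = sum(corr$significant))
    }
  }

  # branch B: pattern taxonomy (depends only on the contrast table) ----------
  if (isTRUE(config$stages$patterns)) {
    pats <- run_stage(report, "patterns",
                      classify_gene_patterns(de$table, params))
    summ <- summarize_patterns(pats)
    bundle$patterns <- as.data.frame(pats)
    bundle$pattern_summary <- data.frame(flag = names(summ$counts),
                                         count = as.integer(summ$counts),
                                         stringsAsFactors = FALSE)
    headline$pattern_counts <- as.list(summ$counts)
    report$stages$patterns <- list(counts = as.list(summ$counts))
  }

  write_results(bundle, out_dir)
  report$headline <- headline
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
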