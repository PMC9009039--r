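# Local pathway over-representation analysis against a user-supplied GMT,
# with the shared/unique overlap partition and annotation-coverage statistics.

#' Hypergeometric over-representation analysis
#'
#' For each pathway, tests whether the cluster's genes over-represent the
#' pathway within the universe: with overlap `k`, pathway size `K` (in the
#' universe), selection size `n` and universe size `N`, the p-value is the
#' hypergeometric upper tail `P(X >= k)`. Pathways with no overlap report
#' p = 1. The EASE variant (`ease = TRUE`) scores the upper tail at `k - 1`,
#' a conservative penalisation of single-gene overlaps. BH adjustment is
#' applied across pathways.
#'
#' @param cluster_genes Character vector of genes in the cluster.
#' @param pathways Pathway collection from [read_gmt()].
#' @param universe Character vector of background genes (default in the
#'   pipeline: all probe sets carrying at least one pathway annotation).
#' @param ease Use the EASE-style `k - 1` tail (default `FALSE`).
#' @return Data frame per pathway: `pathway`, `name`, `k`, `K`, `n`, `N`,
#'   `p`, `p_adj`, `genes` (comma-joined overlap).
#' @export
ora <- function(cluster_genes, pathways, universe, ease = FALSE) {
  universe <- unique(universe)
  if (!length(universe)) ifl_stop("validation", "universe must not be empty")
  sel <- intersect(unique(cluster_genes), universe)
  N <- length(universe)
  n <- length(sel)
  rows <- lapply(names(pathways), function(id) {
    pw <- intersect(pathways[[id]]$genes, universe)
    K <- length(pw)
    hit <- intersect(sel, pw)
    k <- length(hit)
    kk <- if (ease) max(k - 1L, 0L) else k
    p <- stats::phyper(kk - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = id, name = pathways[[id]]$name,
               k = k, K = K, n = n, N = N, p = p,
               genes = paste(sort(hit), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- adjust_bh(out$p)
  out[c("pathway", "name", "k", "K", "n", "N", "p", "p_adj", "genes")]
}

#' Shared/unique partition of enriched-pathway genes
#'
#' Among a cluster's significant pathways, splits each pathway's overlap genes
#' into those unique to that pathway and those shared with at least one other
#' significant pathway.
#'
#' @param table An [ora()] table for one cluster.
#' @param significance `p_adj` threshold defining the enriched pathways
#'   (default 0.05).
#' @return Data frame per enriched pathway: `pathway`, `k`, `unique_count`,
#'   `shared_count` (`unique + shared = k`).
#' @export
shared_unique <- function(table, significance = 0.05) {
  sig <- table[table$p_adj < significance & table$k > 0, , drop = FALSE]
  if (!nrow(sig))
    return(data.frame(pathway = character(0), k = integer(0),
                      unique_count = integer(0), shared_count = integer(0)))
  gene_lists <- strsplit(sig$genes, ",", fixed = TRUE)
  occurrence <- table(unlist(gene_lists))
  res <- lapply(seq_len(nrow(sig)), function(i) {
    g <- gene_lists[[i]]
    u <- sum(occurrence[g] == 1L)
    data.frame(pathway = sig$pathway[i], k = sig$k[i],
               unique_count = u, shared_count = length(g) - u,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Annotation coverage statistics for a cluster
#'
#' @param cluster_genes Character vector of cluster genes.
#' @param pathways Pathway collection.
#' @param enrichment Optional [ora()] table; when given, the "tested" fraction
#'   counts genes appearing in at least one significant pathway.
#' @param significance `p_adj` threshold used with `enrichment`.
#' @return Named numeric vector `covered_fraction` (cluster genes in any
#'   pathway / cluster size) and `tested_fraction` (genes in a significant
#'   pathway / covered genes).
#' @export
coverage_stats <- function(cluster_genes, pathways, enrichment = NULL,
                           significance = 0.05) {
  cluster_genes <- unique(cluster_genes)
  all_annot <- unique(unlist(lapply(pathways, `[[`, "genes")))
  covered <- intersect(cluster_genes, all_annot)
  covered_fraction <- if (length(cluster_genes)) length(covered) / length(cluster_genes) else 0
  tested_fraction <- 0
  if (length(covered) && !is.null(enrichment)) {
    sig <- enrichment[enrichment$p_adj < significance & enrichment$k > 0, , drop = FALSE]
    tested_genes <- unique(unlist(strsplit(sig$genes, ",", fixed = TRUE)))
    tested_fraction <- length(intersect(covered, tested_genes)) / length(covered)
  }
  c(covered_fraction = covered_fraction, tested_fraction = tested_fraction)
}
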