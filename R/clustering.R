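# Two-way hierarchical clustering of the filtered genes and the fixed-k cut.

#' Standardize expression rows
#'
#' Per gene: subtract the mean and divide by the standard deviation across
#' arrays (the usual heatmap convention). Zero-variance rows become all-zero
#' with a warning.
#'
#' @param matrix Expression matrix (typically restricted to the DEG set).
#' @return Row-standardized matrix.
#' @export
standardize_rows <- function(matrix) {
  stopifnot_numeric_matrix(matrix, "matrix")
  mu <- rowMeans(matrix)
  centered <- matrix - mu
  sdv <- sqrt(rowSums(centered^2) / (ncol(matrix) - 1))
  zero <- sdv == 0
  if (any(zero)) {
    warning(sprintf("%d zero-variance row(s) standardized to all-zero", sum(zero)))
    sdv[zero] <- 1
  }
  out <- centered / sdv
  out[zero, ] <- 0
  out
}

cluster_dist <- function(m, distance) {
  switch(distance,
         euclidean = stats::dist(m),
         one_minus_pearson = stats::as.dist(1 - stats::cor(t(m))))
}

hclust_method <- function(linkage) {
  switch(linkage, complete = "complete", average = "average", ward = "ward.D2")
}

#' Hierarchically cluster genes
#'
#' Agglomerative clustering of (standardized) gene rows. Deterministic under a
#' fixed input order; distance ties are resolved by stats::hclust's rule of
#' merging the lowest-index pair first.
#'
#' @param std_matrix Row-standardized gene x array matrix.
#' @param distance `"euclidean"` (default) or `"one_minus_pearson"`.
#' @param linkage `"complete"` (default), `"average"` or `"ward"` (Ward.D2).
#' @return An [stats::hclust] dendrogram.
#' @export
cluster_genes <- function(std_matrix,
                          distance = c("euclidean", "one_minus_pearson"),
                          linkage = c("complete", "average", "ward")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  stats::hclust(cluster_dist(std_matrix, distance), method = hclust_method(linkage))
}

#' Hierarchically cluster samples
#'
#' Same options as [cluster_genes()], applied to the transposed matrix (arrays
#' as observations).
#'
#' @inheritParams cluster_genes
#' @return An [stats::hclust] dendrogram over arrays.
#' @export
cluster_samples <- function(std_matrix,
                            distance = c("euclidean", "one_minus_pearson"),
                            linkage = c("complete", "average", "ward")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  stats::hclust(cluster_dist(t(std_matrix), distance), method = hclust_method(linkage))
}

#' Cut a dendrogram into k clusters
#'
#' Standard k-group cut; cluster ids 1..k are renumbered by dendrogram leaf
#' order (the cluster containing the left-most leaf is 1) for reproducible
#' labels.
#'
#' @param dendrogram An [stats::hclust] object.
#' @param k Number of clusters.
#' @return Named integer vector (leaf label -> cluster id).
#' @export
cut_k <- function(dendrogram, k) {
  n_leaves <- length(dendrogram$order)
  if (k < 1 || k > n_leaves)
    ifl_stop("validation", "k must be between 1 and the number of leaves (%d)", n_leaves)
  raw <- stats::cutree(dendrogram, k)
  leaf_order <- dendrogram$labels[dendrogram$order]
  first_seen <- unique(raw[leaf_order])
  relabel <- stats::setNames(seq_along(first_seen), first_seen)
  out <- relabel[as.character(raw)]
  names(out) <- names(raw)
  out
}

#' Per-cluster mean expression profiles
#'
#' @param std_matrix Row-standardized gene x array matrix.
#' @param assignment Named cluster assignment from [cut_k()] covering the
#'   matrix's genes.
#' @return Cluster x array matrix of mean standardized expression.
#' @export
cluster_means <- function(std_matrix, assignment) {
  if (!all(rownames(std_matrix) %in% names(assignment)))
    ifl_stop("validation", "assignment does not cover all genes in the matrix")
  cl <- assignment[rownames(std_matrix)]
  sums <- rowsum(std_matrix, group = cl)
  out <- sums / as.vector(table(cl)[rownames(sums)])
  out[order(as.integer(rownames(out))), , drop = FALSE]
}

#' Label clusters by their treatment-profile signature
#'
#' Heuristic post-hoc labelling of the k = 4 gene clusters by their mean
#' expression per treatment: clusters down-regulated in the fed states
#' (AL, F2) are labelled 1 (higher in CR than SK) or 2 (higher in SK);
#' clusters up-regulated in the fed states are labelled 3 (not down in SK) or
#' 4 (down in SK).
#'
#' @param cmeans [cluster_means()] matrix.
#' @param sheet Sample sheet for the arrays.
#' @return Named character vector (cluster id -> signature label).
#' @export
label_clusters <- function(cmeans, sheet) {
  treat <- sheet$treatment[match(colnames(cmeans), sheet$array_id)]
  tm <- vapply(TREATMENTS, function(t) rowMeans(cmeans[, treat == t, drop = FALSE]),
               numeric(nrow(cmeans)))
  fed <- (tm[, "AL"] + tm[, "F2"]) / 2
  lab <- ifelse(fed < 0,
                ifelse(tm[, "CR"] >= tm[, "SK"], "1", "2"),
                ifelse(tm[, "SK"] >= 0, "3", "4"))
  stats::setNames(lab, rownames(cmeans))
}
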