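# Readers and writers for the pipeline's external tables. Everything is
# plain TSV (plus GMT for pathways); reader/writer pairs round-trip
# losslessly and writers are byte-stable across runs.

read_tsv_checked <- function(path) {
  if (!file.exists(path)) ifl_stop("io", "file not found: %s", path)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# Full-precision numeric formatting so write/read round-trips are exact to
# double precision for all practical values.
format_full <- function(x) formatC(x, format = "g", digits = 15)

#' Read a probe-level expression table
#'
#' Expects a TSV whose first column holds probe ids and whose remaining
#' columns are arrays.
#'
#' @param path TSV file path.
#' @param log_scale Whether the stored values are already log2; if `FALSE`
#'   all values must be strictly positive (pre-log intensities).
#' @return Numeric matrix (probes x arrays) with a `log2` attribute.
#' @export
read_expression_table <- function(path, log_scale = TRUE) {
  df <- read_tsv_checked(path)
  if (ncol(df) < 2L) ifl_stop("format", "expression table needs probe ids plus >= 1 array")
  ids <- as.character(df[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup))
    ifl_stop("format", "duplicated probe id(s): %s",
             paste(unique(dup), collapse = ", "))
  vals <- df[-1]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad))
        ifl_stop("format", "non-numeric cell at row %d, column '%s'",
                 bad[1], names(vals)[j])
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (any(!is.finite(m))) ifl_stop("format", "expression values must be finite")
  if (!log_scale && any(m <= 0))
    ifl_stop("format", "pre-log intensities must be strictly positive")
  attr(m, "log2") <- isTRUE(log_scale)
  m
}

#' Write an expression matrix as TSV
#'
#' @param m Matrix with probe (or probe-set) row names and array columns.
#' @param path Output file.
#' @param id_column Name for the first (id) column.
#' @export
write_expression_table <- function(m, path, id_column = "probe_id") {
  df <- data.frame(id = rownames(m), stringsAsFactors = FALSE)
  names(df) <- id_column
  for (j in colnames(m)) df[[j]] <- format_full(m[, j])
  write_tsv(df, path)
}

#' Read a probe-to-probe-set map
#' @param path TSV with columns `probe_id`, `probeset_id`.
#' @return Data frame mapping each probe to exactly one probe set.
#' @export
read_probe_map <- function(path) {
  df <- read_tsv_checked(path)
  if (!all(c("probe_id", "probeset_id") %in% names(df)))
    ifl_stop("format", "probe map needs columns probe_id and probeset_id")
  if (anyDuplicated(df$probe_id))
    ifl_stop("format", "probe(s) mapped more than once: %s",
             paste(unique(df$probe_id[duplicated(df$probe_id)]), collapse = ", "))
  df[c("probe_id", "probeset_id")]
}

#' Read a sample sheet
#' @param path TSV with columns `array_id`, `treatment`, `individual_id`.
#' @return Validated data frame; treatments must be in AL, CR, F2, SK.
#' @export
read_sample_sheet <- function(path) {
  df <- read_tsv_checked(path)
  need <- c("array_id", "treatment", "individual_id")
  if (!all(need %in% names(df)))
    ifl_stop("format", "sample sheet needs columns %s", paste(need, collapse = ", "))
  bad <- setdiff(unique(df$treatment), TREATMENTS)
  if (length(bad))
    ifl_stop("validation", "unknown treatment label(s) %s; allowed: %s",
             paste(bad, collapse = ", "), paste(TREATMENTS, collapse = ", "))
  if (anyDuplicated(df$array_id))
    ifl_stop("format", "duplicated array_id in sample sheet")
  if (anyDuplicated(df$individual_id))
    ifl_stop("format", "individual_id must be unique per array")
  df[need]
}

#' Write a sample sheet
#' @param sheet Sample sheet data frame.
#' @param path Output file.
#' @export
write_sample_sheet <- function(sheet, path) write_tsv(sheet, path)

#' Write a probe map
#' @param map Probe map data frame.
#' @param path Output file.
#' @export
write_probe_map <- function(map, path) write_tsv(map, path)

#' Read an individual-level trait table
#'
#' Recognised trait columns are those in [trait_names()]; missing columns are
#' simply absent (all-missing traits). When body mass, liver mass and relative
#' liver mass are all present, relative mass is checked against
#' 100 * liver / body (1% tolerance) with a warning on violation.
#'
#' @param path TSV with `individual_id` plus trait columns.
#' @return Data frame.
#' @export
read_trait_table <- function(path) {
  df <- read_tsv_checked(path)
  if (!"individual_id" %in% names(df))
    ifl_stop("format", "trait table needs an individual_id column")
  keep <- c("individual_id", intersect(trait_names(), names(df)))
  df <- df[keep]
  has3 <- all(c("body_mass", "liver_mass", "relative_liver_mass") %in% names(df))
  if (has3) {
    i <- stats::complete.cases(df[c("body_mass", "liver_mass", "relative_liver_mass")])
    expct <- 100 * df$liver_mass[i] / df$body_mass[i]
    off <- abs(df$relative_liver_mass[i] - expct) > 0.01 * pmax(abs(expct), 1e-12)
    if (any(off))
      warning(sprintf("relative_liver_mass deviates from 100*liver/body for %d individual(s)",
                      sum(off)))
  }
  df
}

#' Write a trait table
#' @param traits Trait table data frame.
#' @param path Output file.
#' @export
write_trait_table <- function(traits, path) {
  out <- traits
  for (j in names(out)) if (is.numeric(out[[j]])) out[[j]] <- format_full(out[[j]])
  write_tsv(out, path)
}

#' Write a planted-truth table
#' @param truth Truth table from [simulate_dataset()].
#' @param path Output file.
#' @export
write_truth <- function(truth, path) {
  out <- truth
  for (j in names(out)) if (is.numeric(out[[j]])) out[[j]] <- format_full(out[[j]])
  write_tsv(out, path)
}

#' Read a planted-truth table
#' @param path TSV written by [write_truth()].
#' @return Data frame.
#' @export
read_truth <- function(path) read_tsv_checked(path)

#' Read a GMT pathway collection
#'
#' Standard GMT: one pathway per line, tab-separated fields
#' `id<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes within a line
#' are deduplicated.
#'
#' @param path GMT file path.
#' @return Named list of pathways, each `list(name = ..., genes = character())`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) ifl_stop("io", "file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      ifl_stop("format", "GMT line %d has fewer than 3 tab-separated fields", i)
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes))
      ifl_stop("format", "GMT line %d (%s) has an empty gene set", i, f[1])
    out[[f[1]]] <- list(name = f[2], genes = genes)
  }
  out
}

#' Write a GMT pathway collection
#' @param pathways Named list as returned by [read_gmt()].
#' @param path Output file.
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(names(pathways), function(id) {
    p <- pathways[[id]]
    paste(c(id, p$name, p$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a bundle of result tables
#'
#' Writes one TSV per table with a fixed column order, floats rounded to six
#' significant digits, and deterministic row ordering (gene id, then contrast
#' pair, where present; otherwise the leading id columns). The same bundle
#' always produces byte-identical files.
#'
#' @param bundle Named list of data frames (e.g. `contrasts`, `deg`,
#'   `clusters`, `patterns`, `enrichment`, `correlations`).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_results <- function(bundle, out_dir) {
  if (!length(bundle)) return(invisible(character(0)))
  if (is.null(names(bundle)) || any(!nzchar(names(bundle))))
    ifl_stop("validation", "bundle must be a named list")
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    ifl_stop("io", "cannot create output directory %s", out_dir)
  paths <- character(0)
  for (nm in names(bundle)) {
    df <- as.data.frame(bundle[[nm]], stringsAsFactors = FALSE)
    key <- intersect(c("gene", "gene_id", "probeset_id", "unit", "cluster",
                       "pathway", "pair", "trait"), names(df))
    if (length(key)) df <- df[do.call(order, df[key]), , drop = FALSE]
    for (j in names(df)) {
      if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
        df[[j]] <- formatC(signif(df[[j]], 6), format = "g", digits = 6)
    }
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    write_tsv(df, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
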