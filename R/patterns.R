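# The expression-pattern taxonomy over the contrast table: broad and strict
# switching, chronic change, their intersection, and the robust chronic class
# that also differs from CR.

#' Classify per-gene expression patterns
#'
#' For each gene, significance `sig(X,Y)` per pair uses the same joint
#' p + fold-change criterion as the inclusion filter (default), or p alone
#' (`sig_mode = "p_only"`); `dir(X,Y)` is the sign of the log2 difference
#' (first-named minus second-named group). Flags:
#'
#' * `switching_broad`: `sig(F2,SK)` and at least one fast-day state differs
#'   from AL.
#' * `switching_strict`: both F2 and SK differ from AL in opposite directions
#'   (and, by default, F2 and SK differ from each other).
#' * `chronic`: both F2 and SK differ from AL in the same direction
#'   (`chronic_direction` up or down).
#' * `chronic_and_switching`: chronic and `sig(F2,SK)`; `chronic_pure`:
#'   chronic and not `sig(F2,SK)`.
#' * `robust_chronic`: chronic and also different from CR in the chronic
#'   direction — in both states by default (`robust_cr = "both"`), or in at
#'   least one (`"any"`).
#'
#' `switching_strict` and `chronic_and_switching` are mutually exclusive
#' (opposite- vs same-direction AL contrasts).
#'
#' @param table A [pairwise_contrasts()] table containing all six pairs for
#'   every gene.
#' @param params [analysis_params()].
#' @param sig_mode `"joint"` (default) or `"p_only"`.
#' @param strict_requires_f2sk Whether strict switching additionally requires
#'   `sig(F2,SK)` (default `TRUE`).
#' @param robust_cr `"both"` (default) or `"any"` CR contrast significant.
#' @return Data frame of class `pattern_calls`: per gene, `sig_*` and `dir_*`
#'   columns for the six pairs plus the pattern flags.
#' @export
classify_gene_patterns <- function(table, params,
                                   sig_mode = c("joint", "p_only"),
                                   strict_requires_f2sk = TRUE,
                                   robust_cr = c("both", "any")) {
  sig_mode <- match.arg(sig_mode)
  robust_cr <- match.arg(robust_cr)
  genes <- unique(table$gene)
  counts <- table(table$gene)
  if (!setequal(unique(table$pair), contrast_pairs()) || any(counts != 6L))
    ifl_stop("validation", "table must contain exactly the six pairs for every gene")

  if (sig_mode == "joint") {
    tab <- flag_passes(table, params)
    sig_long <- tab$passes
  } else {
    pp <- if (params$use_adjusted_p) table$p_adj else table$p
    sig_long <- pp < params$alpha_de
  }
  # wide logical / sign matrices, one row per gene, one column per pair
  idx <- cbind(match(table$gene, genes), match(table$pair, contrast_pairs()))
  sig <- matrix(FALSE, length(genes), 6, dimnames = list(genes, contrast_pairs()))
  dir <- matrix(0, length(genes), 6, dimnames = list(genes, contrast_pairs()))
  sig[idx] <- sig_long
  dir[idx] <- sign(table$delta_log2)

  f2al <- sig[, "F2-AL"]; skal <- sig[, "SK-AL"]; f2sk <- sig[, "F2-SK"]
  same_dir <- dir[, "F2-AL"] == dir[, "SK-AL"]
  switching_broad <- f2sk & (f2al | skal)
  switching_strict <- f2al & skal & !same_dir &
    (if (strict_requires_f2sk) f2sk else TRUE)
  chronic <- f2al & skal & same_dir
  chronic_direction <- ifelse(chronic & dir[, "F2-AL"] > 0, "up",
                              ifelse(chronic & dir[, "F2-AL"] < 0, "down", "none"))
  chronic_and_switching <- chronic & f2sk
  chronic_pure <- chronic & !f2sk
  cdir <- dir[, "F2-AL"]
  cr_ok_f2 <- sig[, "F2-CR"] & dir[, "F2-CR"] == cdir
  cr_ok_sk <- sig[, "SK-CR"] & dir[, "SK-CR"] == cdir
  robust_chronic <- chronic &
    (if (robust_cr == "both") cr_ok_f2 & cr_ok_sk else cr_ok_f2 | cr_ok_sk)

  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (pr in contrast_pairs()) {
    out[[paste0("sig_", gsub("-", "_", pr))]] <- sig[, pr]
    out[[paste0("dir_", gsub("-", "_", pr))]] <- as.integer(dir[, pr])
  }
  out$switching_broad <- switching_broad
  out$switching_strict <- switching_strict
  out$chronic <- chronic
  out$chronic_direction <- chronic_direction
  out$chronic_and_switching <- chronic_and_switching
  out$chronic_pure <- chronic_pure
  out$robust_chronic <- robust_chronic
  class(out) <- c("pattern_calls", "data.frame")
  out
}

pattern_flag_columns <- function() {
  c("switching_broad", "switching_strict", "chronic",
    "chronic_and_switching", "chronic_pure", "robust_chronic")
}

#' Collapse probe-set level calls to gene level
#'
#' Probe sets sharing a gene symbol collapse to one call: a gene inherits a
#' flag if at least one of its probe sets carries it; genes whose probe sets
#' disagree on the chronic direction are flagged `discordant` (direction set
#' to `"none"`, excluded from directional counts).
#'
#' @param calls Probe-set level [classify_gene_patterns()] output.
#' @param symbol_map Optional named vector probe-set id -> gene symbol;
#'   `NULL` (identity) returns the input with a `discordant` column added.
#' @return List with `calls` (gene level) and `duplicates` (symbols mapped by
#'   more than one probe set).
#' @export
dedupe_to_genes <- function(calls, symbol_map = NULL) {
  if (is.null(symbol_map)) {
    out <- calls
    out$discordant <- FALSE
    return(list(calls = out, duplicates = data.frame(symbol = character(0),
                                                     n_probesets = integer(0))))
  }
  sym <- symbol_map[calls$gene]
  sym[is.na(sym)] <- calls$gene[is.na(sym)]
  groups <- split(seq_len(nrow(calls)), sym)
  rows <- lapply(names(groups), function(s) {
    i <- groups[[s]]
    dirs <- setdiff(unique(calls$chronic_direction[i]), "none")
    discordant <- length(dirs) > 1L
    flags <- lapply(pattern_flag_columns(), function(fc) any(calls[[fc]][i]))
    names(flags) <- pattern_flag_columns()
    data.frame(gene = s,
               as.data.frame(flags),
               chronic_direction = if (discordant || !length(dirs)) "none" else dirs,
               discordant = discordant,
               n_probesets = length(i),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("pattern_calls", "data.frame")
  dups <- out[out$n_probesets > 1L, c("gene", "n_probesets")]
  names(dups) <- c("symbol", "n_probesets")
  rownames(dups) <- NULL
  list(calls = out, duplicates = dups)
}

#' Summarize pattern calls
#'
#' Exact set-algebra counts of every flag, directional chronic counts, and
#' Venn-region counts over the four headline comparisons (the three contrasts
#' against AL plus F2 vs SK).
#'
#' @param calls A [classify_gene_patterns()] output (probe-set or gene level).
#' @return List with `counts` (named integer vector) and, when the per-pair
#'   significance columns are present, `venn` (region -> count).
#' @export
summarize_patterns <- function(calls) {
  counts <- c(n_genes = nrow(calls),
              vapply(pattern_flag_columns(), function(fc) sum(calls[[fc]]),
                     integer(1)),
              chronic_up = sum(calls$chronic & calls$chronic_direction == "up"),
              chronic_down = sum(calls$chronic & calls$chronic_direction == "down"),
              strict_also_chronic = sum(calls$switching_strict & calls$chronic))
  venn <- NULL
  venn_pairs <- c("sig_F2_AL", "sig_SK_AL", "sig_CR_AL", "sig_F2_SK")
  if (all(venn_pairs %in% names(calls)) && nrow(calls)) {
    member <- as.matrix(calls[venn_pairs])
    region <- apply(member, 1, function(b) paste(ifelse(b, "1", "0"), collapse = ""))
    venn <- table(region)
  }
  list(counts = counts, venn = venn)
}
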