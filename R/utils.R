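# Internal helpers: classed errors and seed hygiene.

ifl_stop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(paste0("ifliver_", class), "ifliver_error")))
}

# Treatment labels, in canonical column order used throughout.
TREATMENTS <- c("AL", "CR", "F2", "SK")

#' Canonical treatment contrast pairs
#'
#' The six unordered treatment pairs, each stored once with a fixed
#' orientation: the reference state (AL, then CR, then SK) is always the
#' second-named group, so a positive log2 difference means "higher in the
#' first-named group".
#'
#' @return Character vector of the six pair labels.
#' @export
contrast_pairs <- function() {
  c("F2-AL", "SK-AL", "CR-AL", "F2-SK", "F2-CR", "SK-CR")
}

pair_members <- function(pair) strsplit(pair, "-", fixed = TRUE)[[1]]

# Evaluate expr with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so package functions never leak hidden random state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    ifl_stop("validation", "seed must be a single integer")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stopifnot_numeric_matrix <- function(m, what) {
  if (!is.matrix(m) || !is.numeric(m))
    ifl_stop("validation", "%s must be a numeric matrix", what)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    ifl_stop("validation", "%s must have row and column names", what)
  if (any(!is.finite(m)))
    ifl_stop("data", "%s contains non-finite values", what)
  invisible(m)
}
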