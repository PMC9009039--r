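# Synthetic microarray data with planted expression-pattern classes.
#
# The generator follows the standard single-color microarray model: gene-level
# log2 intensities are Gaussian around a gene baseline plus a treatment offset,
# gene-wise true variances are drawn from a scaled inverse-chi-square prior
# (matching the empirical-Bayes moderation downstream), and each probe of a
# probe set adds a small constant probe-specific bias.

#' Planted expression-pattern classes
#'
#' The seven generating classes a synthetic probe set can belong to. AL is
#' always the zero-offset reference state.
#'
#' * `null`: no treatment effect.
#' * `switching_up_in_fast` / `switching_down_in_fast`: opposite-sign F2 and
#'   SK offsets relative to AL (the metabolic-switch profile), with a
#'   same-sign CR offset as in the fasting state, reflecting genes that track
#'   the current energy state.
#' * `chronic_up` / `chronic_down`: equal same-sign F2 and SK offsets.
#' * `chronic_and_switching_up`: same-sign F2 and SK offsets with the SK
#'   offset larger by the planted effect size, so F2 and SK also differ.
#' * `cr_responsive`: offset in both underfed states (CR and SK), none on F2.
#'
#' @return Character vector of class labels.
#' @export
pattern_classes <- function() {
  c("null", "switching_up_in_fast", "switching_down_in_fast",
    "chronic_up", "chronic_down", "chronic_and_switching_up",
    "cr_responsive")
}

#' Canonical trait names
#'
#' The seven physiological traits (liver and body composition) and the three
#' arcuate-nucleus appetite-gene expressions used in the correlation stage.
#'
#' @return Character vector of the ten trait names.
#' @export
trait_names <- function() {
  c("body_mass", "liver_mass", "relative_liver_mass",
    "total_liver_lipids", "liver_lipid_concentration",
    "total_liver_glycogen", "liver_glycogen_concentration",
    "AgRP", "POMC", "NPY")
}

default_class_proportions <- function() {
  c(null = 0.695,
    switching_up_in_fast = 0.09,
    switching_down_in_fast = 0.09,
    chronic_up = 0.015,
    chronic_down = 0.015,
    chronic_and_switching_up = 0.005,
    cr_responsive = 0.09)
}

#' Simulation configuration
#'
#' Builds and validates the configuration of the synthetic-data generator.
#' Defaults reproduce the study design at desk scale: arrays n = 6 (AL),
#' 6 (CR), 4 (F2), 6 (SK); 2--3 probes per probe set; gene variances from a
#' scaled inverse-chi-square prior with `var_prior_d0` degrees of freedom and
#' scale `var_prior_s0sq`; planted offsets of `effect_size_log2` log2 units.
#'
#' @param n_per_treatment Named integer vector of arrays per treatment.
#' @param n_probesets Number of probe sets (genes) to simulate.
#' @param probes_per_set_weights Named probabilities for 2 or 3 probes per set.
#' @param baseline_mean,baseline_sd Gene baseline log2 intensity distribution.
#' @param var_prior_d0,var_prior_s0sq Scaled inverse-chi-square variance prior.
#' @param class_proportions Named probabilities over [pattern_classes()].
#' @param effect_size_log2 Planted offset magnitude (log2 units); must exceed
#'   `log2(1.4)` so planted effects are detectable by design.
#' @param probe_bias_sd Standard deviation of the constant per-probe bias.
#' @param array_shift_sd Standard deviation of an optional global per-array
#'   intensity shift (default 0, i.e. off); exercises the optional
#'   between-array normalization stage.
#' @param seed Integer seed; all randomness is reproducible from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_per_treatment = c(AL = 6L, CR = 6L, F2 = 4L, SK = 6L),
                       n_probesets = 2000L,
                       probes_per_set_weights = c("2" = 0.5, "3" = 0.5),
                       baseline_mean = 8,
                       baseline_sd = 1.5,
                       var_prior_d0 = 4,
                       var_prior_s0sq = 0.05,
                       class_proportions = default_class_proportions(),
                       effect_size_log2 = 0.8,
                       probe_bias_sd = 0.3,
                       array_shift_sd = 0,
                       seed = 1L) {
  if (!all(TREATMENTS %in% names(n_per_treatment)))
    ifl_stop("configuration", "n_per_treatment must name all of %s",
             paste(TREATMENTS, collapse = ", "))
  n_per_treatment <- as.integer(n_per_treatment[TREATMENTS])
  names(n_per_treatment) <- TREATMENTS
  if (any(is.na(n_per_treatment)) || any(n_per_treatment < 2L))
    ifl_stop("design", "every treatment needs >= 2 arrays (variance not estimable otherwise)")
  if (n_probesets < 1L)
    ifl_stop("configuration", "n_probesets must be positive")
  if (!all(names(probes_per_set_weights) %in% c("2", "3")))
    ifl_stop("configuration", "probes_per_set_weights keys must be in {2, 3}")
  if (any(probes_per_set_weights < 0) || abs(sum(probes_per_set_weights) - 1) > 1e-9)
    ifl_stop("configuration", "probes_per_set_weights must be probabilities summing to 1")
  cp <- class_proportions
  if (!all(names(cp) %in% pattern_classes()))
    ifl_stop("configuration", "unknown pattern class in class_proportions: %s",
             paste(setdiff(names(cp), pattern_classes()), collapse = ", "))
  if (any(cp < 0) || abs(sum(cp) - 1) > 1e-9)
    ifl_stop("configuration", "class_proportions must be non-negative and sum to 1")
  if (effect_size_log2 <= log2(1.4))
    ifl_stop("configuration",
             "effect_size_log2 must exceed log2(1.4) = %.4f so planted effects are detectable",
             log2(1.4))
  if (var_prior_d0 <= 0 || var_prior_s0sq <= 0)
    ifl_stop("configuration", "variance prior parameters must be positive")
  structure(list(n_per_treatment = n_per_treatment,
                 n_probesets = as.integer(n_probesets),
                 probes_per_set_weights = probes_per_set_weights,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 var_prior_d0 = var_prior_d0, var_prior_s0sq = var_prior_s0sq,
                 class_proportions = cp,
                 effect_size_log2 = effect_size_log2,
                 probe_bias_sd = probe_bias_sd,
                 array_shift_sd = array_shift_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Treatment offsets for a pattern class
#'
#' @param class A label from [pattern_classes()].
#' @param effect_size_log2 Planted offset magnitude.
#' @return Named numeric vector of log2 offsets for AL, CR, F2, SK
#'   (AL is always 0).
#' @export
class_offsets <- function(class, effect_size_log2) {
  e <- effect_size_log2
  off <- switch(class,
    null                     = c(0, 0, 0, 0),
    switching_up_in_fast     = c(0, e, -e, e),
    switching_down_in_fast   = c(0, -e, e, -e),
    chronic_up               = c(0, 0, e, e),
    chronic_down             = c(0, 0, -e, -e),
    chronic_and_switching_up = c(0, 0, e, 2 * e),
    cr_responsive            = c(0, e, 0, e),
    ifl_stop("validation", "unknown pattern class '%s'", class))
  names(off) <- TREATMENTS
  off
}

#' Simulate a probe-level microarray dataset with planted truth
#'
#' Generates probe intensities, the probe-to-probe-set map, the sample sheet,
#' and a planted-truth table recording every gene's generating class, offsets
#' and true variance. Identical configurations (including the seed) give
#' bit-identical output.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `if_simulation` with elements `probe_matrix`
#'   (probes x arrays, log2 scale), `probe_map`, `sample_sheet`, and `truth`.
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "sim_config"))
    ifl_stop("configuration", "config must be built by sim_config()")
  with_seed(config$seed, {
    G <- config$n_probesets
    npt <- config$n_per_treatment
    A <- sum(npt)
    treat <- rep(TREATMENTS, npt)
    array_id <- sprintf("AR%02d", seq_len(A))
    individual_id <- sprintf("IND%02d", seq_len(A))
    sheet <- data.frame(array_id = array_id, treatment = treat,
                        individual_id = individual_id,
                        stringsAsFactors = FALSE)

    probeset_id <- sprintf("PS%05d", seq_len(G))
    sizes <- sample(c(2L, 3L), G, replace = TRUE,
                    prob = config$probes_per_set_weights[c("2", "3")])
    cls <- sample(names(config$class_proportions), G, replace = TRUE,
                  prob = config$class_proportions)
    true_var <- if (is.finite(config$var_prior_d0)) {
      config$var_prior_d0 * config$var_prior_s0sq /
        stats::rchisq(G, config$var_prior_d0)
    } else rep(config$var_prior_s0sq, G)
    baseline <- stats::rnorm(G, config$baseline_mean, config$baseline_sd)
    offsets <- t(vapply(cls, class_offsets, numeric(4),
                        effect_size_log2 = config$effect_size_log2))
    colnames(offsets) <- TREATMENTS

    # gene x array signal: baseline + treatment offset + array-level noise
    gene_mat <- baseline + offsets[, treat, drop = FALSE] +
      matrix(stats::rnorm(G * A, 0, sqrt(true_var)), G, A)

    gene_of_probe <- rep(seq_len(G), sizes)
    probe_id <- paste0(probeset_id[gene_of_probe], "_p",
                       sequence(sizes))
    bias <- stats::rnorm(length(probe_id), 0, config$probe_bias_sd)
    probe_mat <- gene_mat[gene_of_probe, , drop = FALSE] + bias
    if (config$array_shift_sd > 0) {
      shift <- stats::rnorm(A, 0, config$array_shift_sd)
      probe_mat <- sweep(probe_mat, 2, shift, "+")
    }
    dimnames(probe_mat) <- list(probe_id, array_id)
    attr(probe_mat, "log2") <- TRUE

    truth <- data.frame(gene_id = probeset_id, class = cls,
                        offset_AL = offsets[, "AL"], offset_CR = offsets[, "CR"],
                        offset_F2 = offsets[, "F2"], offset_SK = offsets[, "SK"],
                        true_variance = true_var,
                        stringsAsFactors = FALSE, row.names = NULL)
    structure(list(probe_matrix = probe_mat,
                   probe_map = data.frame(probe_id = probe_id,
                                          probeset_id = probeset_id[gene_of_probe],
                                          stringsAsFactors = FALSE),
                   sample_sheet = sheet,
                   truth = truth),
              class = "if_simulation")
  })
}

#' Planted four-group cluster labels
#'
#' Maps the generating classes onto the four expression archetypes the k = 4
#' gene-cluster cut is expected to recover: underfed-induced
#' (`switching_up_in_fast` and `cr_responsive`, whose standardized profiles
#' correlate at 0.90), fed-induced (`switching_down_in_fast`), chronically
#' up (`chronic_up` with `chronic_and_switching_up`, correlation 0.92) and
#' chronically down (`chronic_down`). Null genes belong to no archetype and
#' get `NA`.
#'
#' @param truth The `truth` table from [simulate_dataset()].
#' @return Named character vector (gene id -> group label, `NA` for null).
#' @export
planted_four_groups <- function(truth) {
  map <- c(switching_up_in_fast = "underfed_induced",
           cr_responsive = "underfed_induced",
           switching_down_in_fast = "fed_induced",
           chronic_up = "chronic_up",
           chronic_and_switching_up = "chronic_up",
           chronic_down = "chronic_down")
  out <- unname(map[truth$class])
  names(out) <- truth$gene_id
  out
}

default_trait_centers <- function() {
  c(body_mass = 400, liver_mass = 10, relative_liver_mass = 2.5,
    total_liver_lipids = 250, liver_lipid_concentration = 25,
    total_liver_glycogen = 150, liver_glycogen_concentration = 15,
    AgRP = 1, POMC = 1, NPY = 1)
}

#' Simulate an individual-level trait table with planted correlations
#'
#' Each planted trait is `center + noise_sd * (r * z + sqrt(1 - r^2) * eps)`
#' where `z` is the standardized archetype score and `eps` standard normal
#' noise, so the sample correlation converges to the planted `r`. Traits not
#' named in `specs` are generated as pure noise (r = 0). To keep the
#' relative-liver-mass identity (100 * liver / body) exact, `liver_mass` is
#' derived from `body_mass` and `relative_liver_mass` (or
#' `relative_liver_mass` derived instead when `liver_mass` itself is planted);
#' planting both is rejected.
#'
#' @param archetype_scores Named numeric vector of per-individual archetype
#'   scores (e.g. a row of [cluster_means()] mapped to individuals).
#' @param specs Data frame with columns `trait_name`, `planted_r` and
#'   optionally `noise_sd` (defaults to 10% of the trait center).
#' @param seed Integer seed.
#' @return Data frame with `individual_id` and the ten trait columns.
#' @export
simulate_traits <- function(archetype_scores, specs, seed = 1L) {
  if (is.null(names(archetype_scores)) || anyDuplicated(names(archetype_scores)))
    ifl_stop("validation", "archetype_scores must be uniquely named by individual")
  if (!all(c("trait_name", "planted_r") %in% names(specs)))
    ifl_stop("validation", "specs needs columns trait_name and planted_r")
  bad <- setdiff(specs$trait_name, trait_names())
  if (length(bad))
    ifl_stop("validation", "unknown trait name(s): %s (allowed: %s)",
             paste(bad, collapse = ", "), paste(trait_names(), collapse = ", "))
  if (anyDuplicated(specs$trait_name))
    ifl_stop("validation", "duplicated trait_name in specs")
  if (any(abs(specs$planted_r) > 1))
    ifl_stop("validation", "|planted_r| must be <= 1")
  if (all(c("liver_mass", "relative_liver_mass") %in% specs$trait_name))
    ifl_stop("validation",
             "cannot plant correlations on both liver_mass and relative_liver_mass (one is derived)")

  centers <- default_trait_centers()
  z <- as.numeric(scale(archetype_scores))
  n <- length(z)
  with_seed(seed, {
    out <- data.frame(individual_id = names(archetype_scores),
                      stringsAsFactors = FALSE)
    derived <- if ("liver_mass" %in% specs$trait_name) "relative_liver_mass" else "liver_mass"
    for (tr in trait_names()) {
      if (tr == derived) { out[[tr]] <- NA_real_; next }
      i <- match(tr, specs$trait_name)
      r <- if (is.na(i)) 0 else specs$planted_r[i]
      sdv <- if (!is.na(i) && "noise_sd" %in% names(specs) && !is.na(specs$noise_sd[i]))
        specs$noise_sd[i] else 0.1 * centers[[tr]]
      if (sdv <= 0) ifl_stop("validation", "noise_sd must be positive for %s", tr)
      eps <- stats::rnorm(n)
      out[[tr]] <- centers[[tr]] + sdv * (r * z + sqrt(1 - r^2) * eps)
    }
    if (derived == "liver_mass") {
      out$liver_mass <- out$body_mass * out$relative_liver_mass / 100
    } else {
      out$relative_liver_mass <- 100 * out$liver_mass / out$body_mass
    }
    out
  })
}

#' Inject outlier arrays into a probe matrix
#'
#' Adds a global intensity shift to the named arrays and optionally permutes
#' their values in place (destroying inter-array correlation), to exercise the
#' array quality-control rule. All other arrays are untouched.
#'
#' @param probe_matrix Probes x arrays matrix.
#' @param array_ids Arrays to corrupt.
#' @param shift Global log2 intensity shift added to those arrays.
#' @param scramble If `TRUE`, each named array's values are randomly permuted.
#' @param seed Integer seed (used only when scrambling).
#' @return The modified matrix.
#' @export
inject_outlier_arrays <- function(probe_matrix, array_ids, shift = 0,
                                  scramble = FALSE, seed = 1L) {
  missing_ids <- setdiff(array_ids, colnames(probe_matrix))
  if (length(missing_ids))
    ifl_stop("validation", "unknown array id(s): %s",
             paste(missing_ids, collapse = ", "))
  with_seed(seed, {
    for (a in array_ids) {
      v <- probe_matrix[, a] + shift
      if (scramble) v <- sample(v)
      probe_matrix[, a] <- v
    }
    probe_matrix
  })
}
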