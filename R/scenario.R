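#' Population templates for the synthetic generator
#'
#' A template defines one ground-truth cell population: its Boolean CAF
#' marker profile, whether it is a lineage-positive contaminant, its
#' stained fluorescence level and its scatter position. Fluorescence for a
#' positive marker is lognormal, parameterised by the arithmetic mean and
#' coefficient of variation; negative markers emit nothing (events still
#' receive autofluorescence and spillover downstream).
#'
#' @param name unique population name.
#' @param positive_markers character vector, subset of [caf_markers()]
#'   (empty for all-negative populations).
#' @param lineage_positive does the population stain in the lineage dump
#'   channel (immune/endothelial/epithelial contaminants)?
#' @param viable if `FALSE` the whole population is dead (bright
#'   viability-dye signal) regardless of the scenario's `dead_fraction`.
#' @param level_mean mean stained signal (a.u.); scalar or named by marker.
#' @param level_cv coefficient of variation of the stained signal.
#' @param scatter_mean length-2 vector, mean (FSC, SSC) area signal.
#' @return An object of class `population_template`.
#' @export
population_template <- function(name, positive_markers = character(0),
                                lineage_positive = FALSE, viable = TRUE,
                                level_mean = 20000, level_cv = 0.5,
                                scatter_mean = c(60000, 25000)) {
  if (!all(positive_markers %in% caf_markers()))
    abort2("unknown marker(s): ",
           paste(setdiff(positive_markers, caf_markers()), collapse = ", "),
           class = "scenario_error")
  if (any(level_cv < 0) || any(level_mean <= 0))
    abort2("level_mean must be > 0 and level_cv >= 0",
           class = "scenario_error")
  lm <- if (length(level_mean) == 1)
    stats::setNames(rep(level_mean, 6), caf_markers()) else level_mean
  if (!all(caf_markers() %in% names(lm)))
    abort2("named level_mean must cover all six markers",
           class = "scenario_error")
  structure(list(name = name,
                 bits = stats::setNames(caf_markers() %in% positive_markers,
                                        caf_markers()),
                 lineage_positive = isTRUE(lineage_positive),
                 viable = isTRUE(viable),
                 level_mean = lm[caf_markers()], level_cv = level_cv,
                 scatter_mean = scatter_mean),
            class = "population_template")
}

#' Scenario configuration: ground truth for the synthetic generator
#'
#' A scenario pins down everything the generator needs: the population
#' templates, their abundances per (tumour type, day), the
#' autofluorescence baseline, the true spillover matrix, doublet and dead
#' rates, per-batch channel gains and the per-sample event count. All
#' randomness flows from `seed` through per-sample derived seeds, so
#' adding samples to a design never perturbs existing ones.
#'
#' @param populations list of [population_template()]s (unique names).
#' @param abundance data frame with columns `tumour_type`, `day`,
#'   `population`, `fraction`; fractions must sum to 1 within each
#'   (tumour_type, day).
#' @param autofluorescence_mean,autofluorescence_sd baseline signal (a.u.)
#'   added to every fluorescence channel; the draw is normal truncated at
#'   0.
#' @param spillover true mixing matrix over the panel's fluorescence
#'   detectors (see [spillover_matrix()]).
#' @param doublet_rate,dead_fraction event-level probabilities in `[0,1)`.
#' @param batch_gains named list: batch id to multiplicative gain, scalar
#'   or named per fluorescence detector; all gains must be positive.
#' @param events_per_sample events drawn per sample before any gating.
#' @param abundance_cv optional per-sample lognormal jitter applied to the
#'   abundance vector (then renormalised); 0 means every sample of a
#'   condition shares the configured composition exactly. Used by the
#'   power/calibration studies; recovery checks keep it at 0.
#' @param scatter_cv scatter noise, as CV of the template scatter means.
#' @param viability_level_mean,viability_level_cv dead-cell dye signal.
#' @param lineage_level_mean,lineage_level_cv dump-channel signal of
#'   lineage-positive populations.
#' @param panel the detector panel (see [default_panel()]).
#' @param seed master seed for the scenario.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(populations, abundance,
                            autofluorescence_mean = 100,
                            autofluorescence_sd = 30,
                            spillover = NULL,
                            doublet_rate = 0.03, dead_fraction = 0.10,
                            batch_gains = list(rep1 = 1),
                            events_per_sample = 50000,
                            abundance_cv = 0,
                            scatter_cv = 0.06,
                            viability_level_mean = 10000,
                            viability_level_cv = 0.4,
                            lineage_level_mean = 8000,
                            lineage_level_cv = 0.4,
                            panel = default_panel(), seed = 1L) {
  validate_panel(panel)
  if (is.null(names(populations)))
    names(populations) <- vapply(populations, `[[`, "", "name")
  if (anyDuplicated(names(populations)))
    abort2("population names must be unique", class = "scenario_error")
  req <- c("tumour_type", "day", "population", "fraction")
  if (!is.data.frame(abundance) || !all(req %in% names(abundance)))
    abort2("abundance needs columns ", paste(req, collapse = ", "),
           class = "scenario_error")
  if (!all(abundance$population %in% names(populations)))
    abort2("abundance references unknown population(s)",
           class = "scenario_error")
  sums <- tapply(abundance$fraction,
                 interaction(abundance$tumour_type, abundance$day,
                             drop = TRUE), sum)
  if (any(abs(sums - 1) > 1e-9))
    abort2("abundance fractions must sum to 1 within each ",
           "(tumour_type, day); got ",
           paste(sprintf("%s=%.6f", names(sums), sums)[abs(sums - 1) > 1e-9],
                 collapse = ", "),
           class = "scenario_validation_error")
  if (doublet_rate < 0 || doublet_rate >= 1 ||
      dead_fraction < 0 || dead_fraction >= 1)
    abort2("doublet_rate and dead_fraction must lie in [0, 1)",
           class = "scenario_error")
  if (any(unlist(batch_gains) <= 0))
    abort2("batch gains must be positive", class = "scenario_error")
  fl <- fluor_detectors(panel)
  if (is.null(spillover)) spillover <- spillover_matrix(diag(length(fl)), fl)
  if (!setequal(spillover$channels, fl))
    abort2("spillover channels must match the panel's fluorescence ",
           "detectors", class = "scenario_error")
  for (p in populations) {
    if (any(p$level_mean[p$bits] <= autofluorescence_mean))
      abort2("population ", p$name, ": positive level mean must exceed ",
             "the autofluorescence mean", class = "scenario_error")
  }
  structure(list(populations = populations, abundance = abundance,
                 autofluorescence_mean = autofluorescence_mean,
                 autofluorescence_sd = autofluorescence_sd,
                 spillover = spillover, doublet_rate = doublet_rate,
                 dead_fraction = dead_fraction, batch_gains = batch_gains,
                 events_per_sample = events_per_sample,
                 abundance_cv = abundance_cv, scatter_cv = scatter_cv,
                 viability_level_mean = viability_level_mean,
                 viability_level_cv = viability_level_cv,
                 lineage_level_mean = lineage_level_mean,
                 lineage_level_cv = lineage_level_cv,
                 panel = panel, seed = as.integer(seed)),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  conds <- unique(x$abundance[c("tumour_type", "day")])
  cat(sprintf(paste0("<scenario_config> %d populations, %d conditions, ",
                     "%d batches, %s events/sample\n"),
              length(x$populations), nrow(conds),
              length(x$batch_gains),
              format(x$events_per_sample, big.mark = ",")))
  invisible(x)
}

#' The default tumour-study scenario
#'
#' Emulates the qualitative biology of murine triple-negative breast
#' tumours (4T1, 4T07) and healthy mammary fat pads: a PDGFRa-dominant
#' fibroblast compartment in healthy tissue that shifts towards
#' FAPa/CD26/PDGFRb-expressing CAF subsets as tumours grow; CD26
#' single-positive CAFs more abundant in 4T07 than 4T1 early (day 7);
#' PDGFRa single-positive CAFs persisting in 4T07 but nearly vanishing in
#' 4T1 by day 21; CD26-expressing subsets rising with time in 4T1 and
#' falling in 4T07 (an interaction between time and tumour type); and
#' 20-40 percent of lineage-negative cells negative for all six markers.
#' Three batches carry distinct multiplicative gains, emulating
#' repeat-to-repeat staining and instrument drift.
#'
#' @param events_per_sample events per simulated sample.
#' @param seed master scenario seed.
#' @param abundance_cv per-sample composition jitter (see
#'   [scenario_config()]).
#' @return A [scenario_config()].
#' @export
#' @examples
#' sc <- default_scenario(events_per_sample = 1000)
#' sc
default_scenario <- function(events_per_sample = 50000, seed = 20260101L,
                             abundance_cv = 0) {
  pops <- list(
    population_template("neg"),
    population_template("pdgfra", "PDGFRa"),
    population_template("pdgfra_pdpn", c("PDGFRa", "PDPN")),
    population_template("cd26", "CD26"),
    population_template("fap", "FAPa"),
    population_template("fap_cd26", c("FAPa", "CD26")),
    population_template("fap_pdgfrb", c("FAPa", "PDGFRb")),
    population_template("asma_pdgfrb", c("aSMA", "PDGFRb")),
    population_template("fap_cd26_pdgfrb", c("FAPa", "CD26", "PDGFRb")),
    population_template("linpos", lineage_positive = TRUE,
                        scatter_mean = c(45000, 20000))
  )
  ab <- function(type, day, fr) {
    data.frame(tumour_type = type, day = day,
               population = names(fr), fraction = unname(fr))
  }
  abundance <- rbind(
    ab("healthy", 0, c(linpos = 0.45, neg = 0.22, pdgfra = 0.25,
                       pdgfra_pdpn = 0.05, asma_pdgfrb = 0.01,
                       fap = 0.01, cd26 = 0.01)),
    ab("4T1", 7, c(linpos = 0.50, neg = 0.15, fap_cd26 = 0.08,
                   fap = 0.06, cd26 = 0.02, pdgfra = 0.05,
                   pdgfra_pdpn = 0.02, fap_pdgfrb = 0.05,
                   asma_pdgfrb = 0.04, fap_cd26_pdgfrb = 0.03)),
    ab("4T1", 14, c(linpos = 0.50, neg = 0.12, fap_cd26 = 0.11,
                    fap = 0.05, cd26 = 0.035, pdgfra = 0.03,
                    pdgfra_pdpn = 0.01, fap_pdgfrb = 0.06,
                    asma_pdgfrb = 0.035, fap_cd26_pdgfrb = 0.05)),
    ab("4T1", 21, c(linpos = 0.50, neg = 0.10, fap_cd26 = 0.13,
                    fap = 0.045, cd26 = 0.05, pdgfra = 0.006,
                    pdgfra_pdpn = 0.004, fap_pdgfrb = 0.07,
                    asma_pdgfrb = 0.035, fap_cd26_pdgfrb = 0.06)),
    ab("4T07", 7, c(linpos = 0.50, neg = 0.14, fap_cd26 = 0.09,
                    fap = 0.04, cd26 = 0.05, pdgfra = 0.07,
                    pdgfra_pdpn = 0.02, fap_pdgfrb = 0.03,
                    asma_pdgfrb = 0.03, fap_cd26_pdgfrb = 0.03)),
    ab("4T07", 14, c(linpos = 0.50, neg = 0.13, fap_cd26 = 0.08,
                     fap = 0.06, cd26 = 0.04, pdgfra = 0.05,
                     pdgfra_pdpn = 0.015, fap_pdgfrb = 0.05,
                     asma_pdgfrb = 0.04, fap_cd26_pdgfrb = 0.035)),
    ab("4T07", 21, c(linpos = 0.50, neg = 0.14, fap_cd26 = 0.06,
                     fap = 0.07, cd26 = 0.03, pdgfra = 0.052,
                     pdgfra_pdpn = 0.018, fap_pdgfrb = 0.06,
                     asma_pdgfrb = 0.045, fap_cd26_pdgfrb = 0.025))
  )
  scenario_config(
    populations = pops, abundance = abundance,
    spillover = default_spillover(),
    batch_gains = list(rep1 = 1.00, rep2 = 1.12, rep3 = 0.92),
    events_per_sample = events_per_sample,
    abundance_cv = abundance_cv, seed = seed
  )
}

#' Default true spillover matrix over the fluorescence detectors
#'
#' Modest leakage between spectrally neighbouring fluorophores, as seen on
#' multi-laser analysers; rows are source channels, columns detectors,
#' diagonal 1.
#'
#' @param panel panel whose fluorescence detectors the matrix covers.
#' @return A [spillover_matrix()].
#' @export
default_spillover <- function(panel = default_panel()) {
  fl <- fluor_detectors(panel)
  k <- length(fl)
  s <- diag(k)
  dimnames(s) <- list(fl, fl)
  pairs <- rbind(
    c("DsRed-A", "PE-A", 0.08), c("PE-A", "DsRed-A", 0.06),
    c("FITC-A", "PE-A", 0.12), c("PE-A", "FITC-A", 0.03),
    c("PE-A", "PE-Cy7-A", 0.04), c("PE-Cy7-A", "APC-Vio770-A", 0.05),
    c("APC-A", "APC-Vio770-A", 0.09), c("APC-Vio770-A", "APC-A", 0.03),
    c("VioBlue-A", "BV711-A", 0.04), c("BV711-A", "APC-Vio770-A", 0.03)
  )
  keep <- pairs[pairs[, 1] %in% fl & pairs[, 2] %in% fl, , drop = FALSE]
  s[cbind(keep[, 1], keep[, 2])] <- as.numeric(keep[, 3])
  spillover_matrix(s, fl)
}

#' The study design mirroring the published sample sizes
#'
#' 128 tumours over three biological repeats (4T1: 21/24/24 and 4T07:
#' 24/21/14 at days 7/14/21) plus 12 healthy fat pads at day 0 spread over
#' two repeats, with per-day group sizes split as evenly as possible
#' across batches.
#'
#' @param batches batch identifiers for the tumour repeats.
#' @return A data frame with columns `sample_id`, `tumour_type`, `day`,
#'   `batch` (one row per sample).
#' @export
default_design <- function(batches = c("rep1", "rep2", "rep3")) {
  sizes <- data.frame(
    tumour_type = c(rep("4T1", 3), rep("4T07", 3), "healthy"),
    day = c(7, 14, 21, 7, 14, 21, 0),
    n = c(21, 24, 24, 24, 21, 14, 12)
  )
  rows <- do.call(rbind, lapply(seq_len(nrow(sizes)), function(i) {
    n <- sizes$n[i]
    b <- if (sizes$tumour_type[i] == "healthy") batches[1:2] else batches
    per <- rep(n %/% length(b), length(b)) +
      (seq_along(b) <= n %% length(b))
    data.frame(tumour_type = sizes$tumour_type[i], day = sizes$day[i],
               batch = rep(b, per))
  }))
  rows$sample_id <- sprintf("%s_D%d_%s_%02d", rows$tumour_type, rows$day,
                            rows$batch,
                            stats::ave(seq_len(nrow(rows)),
                                       rows$tumour_type, rows$day,
                                       rows$batch, FUN = seq_along))
  rows[c("sample_id", "tumour_type", "day", "batch")]
}
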