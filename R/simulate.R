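#' Simulate one stained experimental sample
#'
#' Draws `events_per_sample` cells from the scenario's population mix for
#' the requested (tumour type, day), gives every positive marker a
#' lognormal stained signal, adds a truncated-normal autofluorescence
#' baseline to every fluorescence channel, mixes channels by the true
#' spillover matrix, applies the batch's multiplicative gains, and then
#' overlays the acquisition artefacts: a `doublet_rate` fraction of events
#' are channel-wise sums of two independent cells (pulse widths add while
#' heights take the larger cell's value, so width roughly doubles), and a
#' `dead_fraction` of cells carry a bright viability-dye signal.
#'
#' Determinism: the per-sample seed is derived by hashing
#' (tumour type, day, batch, control kind) into the scenario seed, so the
#' same call always returns the same events and adding other samples to a
#' design never changes this one.
#'
#' @param scenario a [scenario_config()].
#' @param tumour_type,day condition; must exist in the scenario's
#'   abundance map.
#' @param batch batch id; must exist in `scenario$batch_gains`.
#' @param seed override for the derived per-sample seed.
#' @param sample_id identifier stored in the sample metadata.
#' @return A list with `events` (an uncompensated [event_table()]) and
#'   `truth` (a data frame with per-event `population`, the six true
#'   marker bits, and `doublet`, `dead`, `lineage_positive` flags).
#' @export
#' @examples
#' sc <- default_scenario(events_per_sample = 500)
#' s <- simulate_sample(sc, "4T1", 7, "rep1")
#' s$events
#' table(s$truth$population)
simulate_sample <- function(scenario, tumour_type, day, batch,
                            seed = NULL, sample_id = NULL) {
  fr <- condition_fractions(scenario, tumour_type, day)
  gain <- batch_gain_vector(scenario, batch)
  key <- paste(tumour_type, day, batch, "experimental", sep = "|")
  sid <- sample_id %||% sprintf("%s_D%s_%s", tumour_type, day, batch)
  out <- with_seed(seed %||% hash_seed(scenario$seed, key), {
    draw_events(scenario, fr, gain)
  })
  meta <- sample_meta(sid, tumour_type, day, batch)
  list(events = event_table(out$observed, scenario$panel, meta),
       truth = out$truth)
}

#' Simulate a fluorescence-minus-one (FMO) control
#'
#' Identical to [simulate_sample()] except that the omitted marker's
#' antibody is absent: its channel receives only autofluorescence plus
#' spillover from the other stains. FMO tubes are prepared from tumour
#' material, so a condition present in the abundance map is used
#' (defaulting to the scenario's first condition).
#'
#' @inheritParams simulate_sample
#' @param omit_marker the CAF marker left unstained.
#' @return An uncompensated [event_table()] with
#'   `control_kind = "fmo:<marker>"`.
#' @export
simulate_fmo <- function(scenario, omit_marker, batch = NULL,
                         tumour_type = NULL, day = NULL, seed = NULL) {
  if (!omit_marker %in% caf_markers())
    abort2("omit_marker must be one of ",
           paste(caf_markers(), collapse = ", "), class = "scenario_error")
  cond <- unique(scenario$abundance[c("tumour_type", "day")])
  tumour_type <- tumour_type %||% cond$tumour_type[1]
  day <- day %||% cond$day[1]
  batch <- batch %||% names(scenario$batch_gains)[1]
  fr <- condition_fractions(scenario, tumour_type, day)
  gain <- batch_gain_vector(scenario, batch)
  key <- paste(tumour_type, day, batch, paste0("fmo:", omit_marker),
               sep = "|")
  out <- with_seed(seed %||% hash_seed(scenario$seed, key), {
    draw_events(scenario, fr, gain, omit_marker = omit_marker)
  })
  meta <- sample_meta(sprintf("fmo_%s_%s", omit_marker, batch),
                      tumour_type, day, batch,
                      control_kind = paste0("fmo:", omit_marker))
  event_table(out$observed, scenario$panel, meta)
}

#' Simulate the full FMO set for a batch
#'
#' @inheritParams simulate_fmo
#' @return Named list of six FMO [event_table()]s, one per CAF marker.
#' @export
simulate_fmo_set <- function(scenario, batch = NULL, ...) {
  stats::setNames(lapply(caf_markers(), function(m)
    simulate_fmo(scenario, m, batch = batch, ...)), caf_markers())
}

#' Simulate an unstained control
#'
#' No antibodies and no viability dye: every fluorescence channel carries
#' autofluorescence only (mixed and gain-scaled as usual). Used to
#' calibrate the viability and lineage cutoffs by the same tail-count
#' rule as the marker FMOs.
#'
#' @inheritParams simulate_fmo
#' @return An uncompensated [event_table()].
#' @export
simulate_unstained <- function(scenario, batch = NULL, tumour_type = NULL,
                               day = NULL, seed = NULL) {
  cond <- unique(scenario$abundance[c("tumour_type", "day")])
  tumour_type <- tumour_type %||% cond$tumour_type[1]
  day <- day %||% cond$day[1]
  batch <- batch %||% names(scenario$batch_gains)[1]
  fr <- condition_fractions(scenario, tumour_type, day)
  gain <- batch_gain_vector(scenario, batch)
  key <- paste(tumour_type, day, batch, "unstained", sep = "|")
  out <- with_seed(seed %||% hash_seed(scenario$seed, key), {
    draw_events(scenario, fr, gain, stained = FALSE)
  })
  meta <- sample_meta(sprintf("unstained_%s", batch), tumour_type, day,
                      batch, control_kind = "unstained")
  event_table(out$observed, scenario$panel, meta)
}

#' Simulate a single-stain bead control
#'
#' A mixture of bright positive beads and unstained negative beads on one
#' primary channel; every other fluorescence channel receives the primary
#' signal times the true spillover coefficient, on top of the
#' autofluorescence baseline. The positive count is fixed by construction
#' at `round(n_events * positive_fraction)`.
#'
#' @param fluorophore primary detector (a fluorescence channel id).
#' @param true_spillover the ground-truth [spillover_matrix()].
#' @param seed RNG seed.
#' @param n_events total bead events.
#' @param positive_fraction fraction of beads that bound antibody; the
#'   default yields 6,000 positive events, comfortably above the 5,000
#'   the acquisition protocol requires.
#' @param positive_level,positive_cv lognormal bright-signal parameters.
#' @param autofluorescence_mean,autofluorescence_sd baseline, as in
#'   [scenario_config()].
#' @param panel detector panel.
#' @return An [event_table()] with `control_kind = "beads:<fluorophore>"`.
#' @export
simulate_beads <- function(fluorophore, true_spillover, seed = 1L,
                           n_events = 10000, positive_fraction = 0.6,
                           positive_level = 50000, positive_cv = 0.25,
                           autofluorescence_mean = 100,
                           autofluorescence_sd = 30,
                           panel = default_panel()) {
  fl <- fluor_detectors(panel)
  if (!fluorophore %in% fl)
    abort2("fluorophore must be a fluorescence detector of the panel",
           class = "scenario_error")
  if (!setequal(true_spillover$channels, fl))
    abort2("spillover channels must match the panel", class = "scenario_error")
  n_pos <- round(n_events * positive_fraction)
  with_seed(seed, {
    true <- matrix(0, n_events, length(fl), dimnames = list(NULL, fl))
    true[seq_len(n_pos), fluorophore] <-
      rlnorm_mean_cv(n_pos, positive_level, positive_cv)
    af <- matrix(pmax(stats::rnorm(n_events * length(fl),
                                   autofluorescence_mean,
                                   autofluorescence_sd), 0),
                 n_events, length(fl))
    obs <- (true + af) %*% true_spillover$coefficients[fl, fl]
    m <- matrix(0, n_events, nrow(panel),
                dimnames = list(NULL, panel$detector))
    m[, fl] <- obs
    scatter <- panel$detector[startsWith(panel$role, "scatter")]
    m[, scatter] <- matrix(
      pmax(stats::rnorm(n_events * length(scatter), 40000, 2000), 1),
      n_events, length(scatter))
    meta <- sample_meta(paste0("beads_", fluorophore), "healthy", 0,
                        "comp", control_kind = paste0("beads:", fluorophore))
    event_table(m, panel, meta)
  })
}

#' Simulate a whole study design
#'
#' One experimental sample per design row; sample seeds are derived per
#' sample id so the result is reproducible row by row.
#'
#' @param scenario a [scenario_config()].
#' @param design data frame as from [default_design()].
#' @return Named list (by `sample_id`) of [simulate_sample()] results.
#' @export
simulate_study <- function(scenario, design = default_design()) {
  stats::setNames(lapply(seq_len(nrow(design)), function(i) {
    simulate_sample(scenario, design$tumour_type[i], design$day[i],
                    design$batch[i],
                    seed = hash_seed(scenario$seed, design$sample_id[i]),
                    sample_id = design$sample_id[i])
  }), design$sample_id)
}

# ---- internals -----------------------------------------------------------

condition_fractions <- function(scenario, tumour_type, day) {
  sel <- scenario$abundance$tumour_type == tumour_type &
    scenario$abundance$day == day
  if (!any(sel))
    abort2("no abundance configured for (", tumour_type, ", day ", day,
           ")", class = "scenario_configuration_error")
  stats::setNames(scenario$abundance$fraction[sel],
                  scenario$abundance$population[sel])
}

batch_gain_vector <- function(scenario, batch) {
  g <- scenario$batch_gains[[as.character(batch)]]
  if (is.null(g))
    abort2("unknown batch: ", batch, class = "scenario_configuration_error")
  fl <- fluor_detectors(scenario$panel)
  if (length(g) == 1) return(stats::setNames(rep(g, length(fl)), fl))
  if (!all(fl %in% names(g)))
    abort2("per-channel batch gains must name every fluorescence detector",
           class = "scenario_error")
  g[fl]
}

# lognormal draws parameterised by arithmetic mean and CV; cv = 0
# degenerates to the constant mean
rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, log(mean) - sdlog^2 / 2, sdlog)
}

# draw n observed events + ground truth under the current RNG state
draw_events <- function(scenario, fractions, gain,
                        omit_marker = NULL, stained = TRUE) {
  n <- scenario$events_per_sample
  if (scenario$abundance_cv > 0) {
    sdlog <- sqrt(log(1 + scenario$abundance_cv^2))
    jit <- fractions * stats::rlnorm(length(fractions), -sdlog^2 / 2, sdlog)
    fractions <- jit / sum(jit)
  }
  first <- draw_singlets(scenario, fractions, gain, n, omit_marker, stained)
  dbl <- stats::runif(n) < scenario$doublet_rate
  if (any(dbl)) {
    partner <- draw_singlets(scenario, fractions, gain, sum(dbl),
                             omit_marker, stained)
    heights <- scenario$panel$detector[
      scenario$panel$role == "scatter_height"]
    comb <- first$observed[dbl, , drop = FALSE] + partner$observed
    comb[, heights] <- pmax(first$observed[dbl, heights, drop = FALSE],
                            partner$observed[, heights, drop = FALSE])
    first$observed[dbl, ] <- comb
    first$truth$dead[dbl] <- first$truth$dead[dbl] | partner$truth$dead
    first$truth$lineage_positive[dbl] <-
      first$truth$lineage_positive[dbl] | partner$truth$lineage_positive
  }
  first$truth$doublet <- dbl
  first$truth <- first$truth[c("population", caf_markers(), "doublet",
                               "dead", "lineage_positive")]
  first
}

draw_singlets <- function(scenario, fractions, gain, n,
                          omit_marker = NULL, stained = TRUE) {
  pops <- scenario$populations[names(fractions)]
  idx <- sample(seq_along(pops), n, replace = TRUE, prob = fractions)
  panel <- scenario$panel
  fl <- fluor_detectors(panel)
  via <- panel_detector(panel, "viability")
  dump <- panel_detector(panel, "lineage_dump")

  true <- matrix(0, n, length(fl), dimnames = list(NULL, fl))
  bits <- matrix(FALSE, n, 6, dimnames = list(NULL, caf_markers()))
  linpos <- logical(n)
  dead <- if (scenario$dead_fraction > 0)
    stats::runif(n) < scenario$dead_fraction else logical(n)
  fsc <- numeric(n); ssc <- numeric(n)

  for (p in seq_along(pops)) {
    rows <- which(idx == p)
    if (length(rows) == 0) next
    tpl <- pops[[p]]
    bits[rows, ] <- matrix(tpl$bits, length(rows), 6, byrow = TRUE)
    linpos[rows] <- tpl$lineage_positive
    if (!tpl$viable) dead[rows] <- TRUE
    if (stained) {
      for (m in caf_markers()[tpl$bits]) {
        if (identical(m, omit_marker)) next
        det <- panel_detector(panel, "caf_marker", m)
        true[rows, det] <- rlnorm_mean_cv(length(rows),
                                          tpl$level_mean[[m]], tpl$level_cv)
      }
      if (tpl$lineage_positive)
        true[rows, dump] <- rlnorm_mean_cv(length(rows),
                                           scenario$lineage_level_mean,
                                           scenario$lineage_level_cv)
    }
    s_cv <- scenario$scatter_cv
    fsc[rows] <- stats::rnorm(length(rows), tpl$scatter_mean[1],
                              s_cv * tpl$scatter_mean[1])
    ssc[rows] <- stats::rnorm(length(rows), tpl$scatter_mean[2],
                              s_cv * tpl$scatter_mean[2])
  }
  if (stained && any(dead))
    true[dead, via] <- rlnorm_mean_cv(sum(dead),
                                      scenario$viability_level_mean,
                                      scenario$viability_level_cv)
  af <- matrix(pmax(stats::rnorm(n * length(fl),
                                 scenario$autofluorescence_mean,
                                 scenario$autofluorescence_sd), 0),
               n, length(fl))
  obs_fl <- ((true + af) %*% scenario$spillover$coefficients[fl, fl]) *
    rep(gain, each = n)

  m <- matrix(0, n, nrow(panel), dimnames = list(NULL, panel$detector))
  m[, fl] <- obs_fl
  fsc <- pmax(fsc, 1); ssc <- pmax(ssc, 1)
  m[, panel_detector(panel, "scatter_area")[1]] <- fsc
  m[, panel_detector(panel, "scatter_area")[2]] <- ssc
  m[, panel_detector(panel, "scatter_height")[1]] <- 0.6 * fsc
  m[, panel_detector(panel, "scatter_height")[2]] <- 0.6 * ssc
  w_cv <- scenario$scatter_cv
  m[, panel_detector(panel, "scatter_width")[1]] <-
    pmax(stats::rnorm(n, 70, w_cv * 70), 1)
  m[, panel_detector(panel, "scatter_width")[2]] <-
    pmax(stats::rnorm(n, 70, w_cv * 70), 1)

  truth <- data.frame(population = names(pops)[idx],
                      stringsAsFactors = FALSE)
  truth <- cbind(truth, as.data.frame(bits))
  truth$dead <- dead
  truth$lineage_positive <- linpos
  list(observed = m, truth = truth)
}
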