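#' Calibrate a marker threshold from an FMO control
#'
#' The published gating rule: the gate is placed so that no more than
#' 0.03 percent of the FMO control's events fall inside it. The cutoff is
#' the smallest observed event value `v` such that the fraction of events
#' strictly above `v` is at most `q` (a tail-count rule, not an
#' interpolated quantile), so the guarantee holds exactly on the
#' calibration sample itself, ties resolving conservatively upward.
#'
#' @param fmo_live_events numeric vector: the marker-channel values of the
#'   FMO control's live events.
#' @param q admissible tail fraction; default `3e-4` (0.03 percent).
#' @return The cutoff (a.u.). Marker positivity downstream is strict `>`.
#' @export
#' @examples
#' cut <- calibrate_fmo_threshold(1:10000)
#' sum(1:10000 > cut) / 10000  # <= 3e-4 exactly
calibrate_fmo_threshold <- function(fmo_live_events, q = 3e-4) {
  if (length(fmo_live_events) == 0)
    abort2("no events supplied for FMO calibration", class = "gating_error")
  if (!is.numeric(q) || length(q) != 1 || q <= 0 || q > 0.01)
    abort2("q must lie in (0, 0.01]", class = "gating_error")
  n <- length(fmo_live_events)
  if (n < 1 / q)
    warning(sprintf(
      "only %d FMO events for q = %g; at least %d recommended",
      n, q, ceiling(1 / q)))
  # admissible count strictly above the cutoff; the epsilon guards the
  # exact-multiple case (q*n integral) against binary rounding
  k <- floor(q * n + 1e-9)
  sorted <- sort(fmo_live_events)
  sorted[n - k]
}

#' Calibrate all six marker thresholds from an FMO set
#'
#' Each marker's cutoff comes from its own FMO control, using the
#' marker-channel values of that control's live (and optionally singlet,
#' lineage-unrestricted) events. FMO tables are compensated before
#' calibration when a spillover matrix is given.
#'
#' @param fmos named list of FMO [event_table()]s, one per CAF marker.
#' @param spill optional [spillover_matrix()] applied to each FMO first.
#' @param viability_cutoff cutoff used to restrict calibration to live
#'   events, as in the published protocol; `Inf` disables the
#'   restriction.
#' @param q tail fraction, as in [calibrate_fmo_threshold()].
#' @return An `fmo_thresholds` object: named cutoffs plus provenance.
#' @export
calibrate_fmo_set <- function(fmos, spill = NULL,
                              viability_cutoff = Inf, q = 3e-4) {
  if (!setequal(names(fmos), caf_markers()))
    abort2("fmos must be named by the six CAF markers",
           class = "gating_error")
  cuts <- vapply(caf_markers(), function(m) {
    tab <- fmos[[m]]
    if (!is.null(spill) && !tab$compensated)
      tab <- apply_compensation(tab, spill)
    live <- channel_values(tab, "viability") <= viability_cutoff
    calibrate_fmo_threshold(channel_values(tab, "caf_marker", m)[live],
                            q = q)
  }, 0)
  structure(list(cutoffs = cuts, q = q,
                 source = vapply(fmos, function(t)
                   t$meta$sample_id %||% NA_character_, "")),
            class = "fmo_thresholds")
}

#' @export
print.fmo_thresholds <- function(x, ...) {
  cat(sprintf("<fmo_thresholds> q = %g\n", x$q))
  print(round(x$cutoffs, 2))
  invisible(x)
}

#' Exclude doublets by pulse geometry
#'
#' Keeps events whose width-to-height ratio on BOTH scatter channels is
#' at most `width_ratio_limit` times the sample's median ratio. A doublet
#' is two cells in one pulse: its width roughly doubles while its height
#' does not, so its ratio sits near twice the singlet median.
#'
#' @param table an [event_table()] with FSC/SSC height and width
#'   channels.
#' @param width_ratio_limit multiple of the median ratio tolerated;
#'   default 1.5.
#' @return The filtered [event_table()], with attribute `kept` (logical
#'   vector over the input events).
#' @export
exclude_doublets <- function(table, width_ratio_limit = 1.5) {
  panel <- table$panel
  h <- panel$detector[panel$role == "scatter_height"]
  w <- panel$detector[panel$role == "scatter_width"]
  if (length(h) != 2 || length(w) != 2)
    abort2("panel lacks FSC/SSC height and width channels",
           class = "gating_error")
  keep <- rep(TRUE, nrow(table$values))
  for (i in 1:2) {
    ratio <- table$values[, w[i]] / table$values[, h[i]]
    keep <- keep & ratio <= stats::median(ratio) * width_ratio_limit
  }
  out <- subset_events(table, keep)
  attr(out, "kept") <- keep
  out
}

#' Viability and lineage gates
#'
#' `viability_gate` keeps events at or below the viability-dye cutoff
#' (live cells); `lineage_gate` keeps events at or below the dump-channel
#' cutoff (lineage-negative cells).
#'
#' @param table an [event_table()].
#' @param cutoff gate position (a.u.); `Inf` keeps everything.
#' @return The filtered [event_table()] with attribute `kept`.
#' @export
viability_gate <- function(table, cutoff) {
  keep <- channel_values(table, "viability") <= cutoff
  out <- subset_events(table, keep)
  attr(out, "kept") <- keep
  out
}

#' @rdname viability_gate
#' @export
lineage_gate <- function(table, cutoff) {
  keep <- channel_values(table, "lineage_dump") <= cutoff
  out <- subset_events(table, keep)
  attr(out, "kept") <- keep
  out
}

#' Call the six Boolean marker positivities
#'
#' @param lin_neg an [event_table()] of lineage-negative events.
#' @param thresholds an `fmo_thresholds` object (see
#'   [calibrate_fmo_set()]) or a named cutoff vector.
#' @return Events-by-6 logical matrix; positive is strict `>` the cutoff.
#' @export
call_markers <- function(lin_neg, thresholds) {
  cuts <- if (inherits(thresholds, "fmo_thresholds"))
    thresholds$cutoffs else thresholds
  if (!all(caf_markers() %in% names(cuts)))
    abort2("thresholds must cover all six CAF markers",
           class = "gating_error")
  calls <- vapply(caf_markers(), function(m)
    channel_values(lin_neg, "caf_marker", m) > cuts[[m]],
    logical(nrow(lin_neg$values)))
  if (is.null(dim(calls)))
    calls <- matrix(calls, nrow = 1, dimnames = list(NULL, caf_markers()))
  calls
}

#' Apply the full gating tree
#'
#' cells -> singlets -> live -> lineage-negative -> per-marker calls ->
#' CAF+ (positive for at least one of the six markers, Boolean OR) and
#' CAF- (none). The CAF+/CAF- pair partitions the lineage-negative
#' population exactly. Input must be compensated unless
#' `allow_uncompensated = TRUE`.
#'
#' @param sample a compensated [event_table()].
#' @param thresholds marker cutoffs (see [calibrate_fmo_set()]).
#' @param viability_cutoff,lineage_cutoff gate positions (a.u.); see
#'   [calibrate_negative_cutoff()] for the reproducible default rule.
#' @param fsc_range,ssc_range optional rectangle for the initial cell
#'   gate on (FSC-A, SSC-A); defaults pass everything through, as no
#'   debris is simulated unless configured.
#' @param width_ratio_limit singlet gate, see [exclude_doublets()].
#' @param allow_uncompensated skip the compensation check.
#' @return A `gating_result`: per-gate logical membership over the input
#'   events, a population count table, and `marker_calls` for the
#'   lineage-negative events.
#' @export
apply_gating_tree <- function(sample, thresholds,
                              viability_cutoff, lineage_cutoff,
                              fsc_range = c(0, Inf), ssc_range = c(0, Inf),
                              width_ratio_limit = 1.5,
                              allow_uncompensated = FALSE) {
  if (!sample$compensated && !allow_uncompensated)
    abort2("sample is not compensated; pass allow_uncompensated = TRUE ",
           "to override", class = "gating_error")
  n <- nrow(sample$values)
  fsc <- channel_values(sample, "scatter_area")[, 1]
  ssc <- channel_values(sample, "scatter_area")[, 2]
  cells <- fsc >= fsc_range[1] & fsc <= fsc_range[2] &
    ssc >= ssc_range[1] & ssc <= ssc_range[2]

  tab_cells <- subset_events(sample, cells)
  tab_singlets <- exclude_doublets(tab_cells, width_ratio_limit)
  singlets <- cells
  singlets[cells] <- attr(tab_singlets, "kept")

  tab_live <- viability_gate(tab_singlets, viability_cutoff)
  live <- singlets
  live[singlets] <- attr(tab_live, "kept")

  tab_lin <- lineage_gate(tab_live, lineage_cutoff)
  lin_neg <- live
  lin_neg[live] <- attr(tab_lin, "kept")

  calls <- call_markers(tab_lin, thresholds)
  caf_pos_local <- rowSums(calls) > 0
  caf_pos <- lin_neg
  caf_pos[lin_neg] <- caf_pos_local
  caf_neg <- lin_neg & !caf_pos

  membership <- cbind(cells = cells, singlets = singlets, live = live,
                      lin_neg = lin_neg, caf_pos = caf_pos,
                      caf_neg = caf_neg)
  counts <- colSums(membership)
  parents <- c(cells = n, singlets = counts[["cells"]],
               live = counts[["singlets"]], lin_neg = counts[["live"]],
               caf_pos = counts[["lin_neg"]],
               caf_neg = counts[["lin_neg"]])
  summary <- data.frame(
    population = names(counts), count = as.integer(counts),
    parent_count = as.integer(parents),
    pct_of_parent = 100 * counts / pmax(parents, 1),
    pct_of_live = 100 * counts / max(counts[["live"]], 1),
    row.names = NULL)
  structure(list(membership = membership, summary = summary,
                 marker_calls = calls, n_events = n,
                 sample_meta = sample$meta),
            class = "gating_result")
}

#' @export
print.gating_result <- function(x, ...) {
  cat(sprintf("<gating_result> %s: %d events\n",
              x$sample_meta$sample_id %||% "sample", x$n_events))
  print(transform(x$summary,
                  pct_of_parent = round(pct_of_parent, 2),
                  pct_of_live = round(pct_of_live, 2)))
  invisible(x)
}

#' Calibrate viability/lineage cutoffs from an unstained control
#'
#' The published gates were set visually; the reproducible stand-in used
#' here applies the same tail-count rule as the marker FMOs to an
#' unstained (dye- and antibody-free) control, at a looser default tail
#' of 0.5 percent.
#'
#' @param control an unstained [event_table()] (compensated if a
#'   spillover matrix is in play).
#' @param role `"viability"` or `"lineage_dump"`.
#' @param q tail fraction.
#' @return The cutoff (a.u.).
#' @export
calibrate_negative_cutoff <- function(control, role, q = 0.005) {
  calibrate_fmo_threshold(channel_values(control, role), q = q)
}
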