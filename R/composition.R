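#' Enumerate all non-empty Boolean marker subsets
#'
#' With `m` markers there are `2^m - 1` non-empty positive/negative
#' combinations; for the six-marker CAF panel that is 63. Subset `index`
#' is the binary encoding with bit 1 = the first marker in `markers`, so
#' index 1 is "first marker only" and index 63 is all-positive. The
#' all-negative combination (index 0) is the CAF- population and is not a
#' subset.
#'
#' @param markers ordered marker names (1 to 16).
#' @return Data frame with `index`, `label` and one logical column per
#'   marker, ordered by index.
#' @export
#' @examples
#' nrow(enumerate_subsets(caf_markers()))  # 63
enumerate_subsets <- function(markers = caf_markers()) {
  m <- length(markers)
  if (m < 1 || m > 16)
    abort2("between 1 and 16 markers required", class = "composition_error")
  idx <- seq_len(2^m - 1)
  bits <- t(vapply(idx, function(i) as.logical(bitwAnd(i, 2^(0:(m - 1)))),
                   logical(m)))
  colnames(bits) <- markers
  labels <- apply(bits, 1, function(b)
    paste0(markers[b], "+", collapse = ""))
  cbind(data.frame(index = idx, label = labels, stringsAsFactors = FALSE),
        as.data.frame(bits))
}

#' Map marker calls to Boolean subset indices
#'
#' All-negative events map to 0 (the CAF- sentinel); every other call
#' pattern maps to its unique binary index, so the assignment partitions
#' the cells.
#'
#' @param marker_bits logical vector of length `m`, or an events-by-`m`
#'   logical matrix.
#' @param m number of markers (default 6).
#' @return Integer index (0 to `2^m - 1`), vectorised over rows.
#' @export
#' @examples
#' assign_subset(c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))  # 1
assign_subset <- function(marker_bits, m = 6) {
  if (is.matrix(marker_bits)) {
    if (ncol(marker_bits) != m)
      abort2("expected ", m, " marker columns", class = "composition_error")
    return(as.integer(marker_bits %*% 2^(0:(m - 1))))
  }
  if (length(marker_bits) != m)
    abort2("expected ", m, " marker bits", class = "composition_error")
  as.integer(sum(2^(0:(m - 1))[as.logical(marker_bits)]))
}

#' Build a per-sample composition profile
#'
#' Summarises a gated sample: the 63 Boolean subset fractions of the CAF+
#' population, the CAF+ fraction of Lin-, the Lin- fraction of live, the
#' CAF+ fraction of live, and the per-marker fractions of CAF+. The
#' marker-marginal identity holds by construction: the fraction positive
#' for marker `j` equals the summed fractions of every subset containing
#' `j`.
#'
#' @param g a `gating_result` from [apply_gating_tree()].
#' @return A `composition_profile`: list with `sample_id`,
#'   `subset_fractions` (named 63-vector, `NA` when the sample has no
#'   CAF+ cells), `subset_counts`, `n_caf_pos`, `caf_pos_of_lin_neg`,
#'   `lin_neg_of_live`, `caf_pos_of_live`, `per_marker_of_caf_pos` and
#'   the sample metadata.
#' @export
composition_profile <- function(g) {
  if (!inherits(g, "gating_result"))
    abort2("composition_profile expects a gating_result",
           class = "composition_error")
  subsets <- enumerate_subsets(caf_markers())
  idx <- assign_subset(g$marker_calls)
  counts <- tabulate(idx, nbins = 63)          # drops the CAF- zeros
  names(counts) <- subsets$label
  n_caf_pos <- sum(counts)
  cnt <- g$summary$count
  names(cnt) <- g$summary$population
  fr <- function(a, b) if (b > 0) a / b else NA_real_
  fractions <- if (n_caf_pos > 0) counts / n_caf_pos
    else stats::setNames(rep(NA_real_, 63), subsets$label)
  # computed from the subset fractions so the marker-marginal identity
  # holds bitwise, not merely to rounding
  per_marker <- vapply(caf_markers(), function(m)
    sum(fractions[subsets[[m]]]), 0)
  structure(list(
    sample_id = g$sample_meta$sample_id %||% NA_character_,
    meta = g$sample_meta,
    subset_fractions = fractions,
    subset_counts = counts,
    n_caf_pos = n_caf_pos,
    caf_pos_of_lin_neg = fr(cnt[["caf_pos"]], cnt[["lin_neg"]]),
    lin_neg_of_live = fr(cnt[["lin_neg"]], cnt[["live"]]),
    caf_pos_of_live = fr(cnt[["caf_pos"]], cnt[["live"]]),
    per_marker_of_caf_pos = per_marker),
    class = "composition_profile")
}

#' @export
print.composition_profile <- function(x, ...) {
  cat(sprintf("<composition_profile> %s: %d CAF+ cells\n",
              x$sample_id, x$n_caf_pos))
  cat(sprintf("  CAF+/Lin-: %.1f%%  Lin-/live: %.1f%%  CAF+/live: %.1f%%\n",
              100 * x$caf_pos_of_lin_neg, 100 * x$lin_neg_of_live,
              100 * x$caf_pos_of_live))
  top <- sort(x$subset_fractions, decreasing = TRUE)[1:5]
  cat("  top subsets:",
      paste(sprintf("%s %.1f%%", names(top), 100 * top), collapse = ", "),
      "\n")
  invisible(x)
}

# profiles with no CAF+ cells cannot contribute composition vectors
usable_profiles <- function(profiles) {
  ok <- vapply(profiles, function(p) p$n_caf_pos > 0, TRUE)
  if (!all(ok))
    warning(sum(!ok), " profile(s) with no CAF+ cells excluded")
  profiles[ok]
}

profile_matrix <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p) p$subset_fractions))
}

profile_groups <- function(profiles) {
  data.frame(
    sample_id = vapply(profiles, function(p) p$sample_id, ""),
    tumour_type = vapply(profiles, function(p)
      p$meta$tumour_type %||% NA_character_, ""),
    day = vapply(profiles, function(p) p$meta$day %||% NA_integer_, 1L),
    batch = vapply(profiles, function(p)
      p$meta$batch %||% NA_character_, ""),
    stringsAsFactors = FALSE)
}

#' Rank Boolean subsets by mean abundance within groups
#'
#' For each (tumour type, day) group: subsets sorted by mean percentage
#' of CAF+ (descending, ties broken by subset index), with SEM and the
#' cumulative coverage of the top-k subsets.
#'
#' @param profiles list of [composition_profile()]s.
#' @return Data frame with `tumour_type`, `day`, `rank`, `index`,
#'   `label`, `mean_pct`, `sem_pct`, `cum_pct`.
#' @export
abundance_ranking <- function(profiles) {
  profiles <- usable_profiles(profiles)
  grp <- profile_groups(profiles)
  mat <- 100 * profile_matrix(profiles)
  subsets <- enumerate_subsets(caf_markers())
  out <- lapply(split(seq_len(nrow(grp)),
                      list(grp$tumour_type, grp$day), drop = TRUE),
                function(rows) {
    mu <- colMeans(mat[rows, , drop = FALSE])
    sem <- apply(mat[rows, , drop = FALSE], 2, stats::sd) /
      sqrt(length(rows))
    ord <- order(-mu, subsets$index)
    data.frame(tumour_type = grp$tumour_type[rows[1]],
               day = grp$day[rows[1]],
               rank = seq_len(63), index = subsets$index[ord],
               label = subsets$label[ord], mean_pct = mu[ord],
               sem_pct = sem[ord], cum_pct = cumsum(mu[ord]),
               row.names = NULL)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$tumour_type, out$day, out$rank), ]
}

#' Subset-by-sample heatmap matrix
#'
#' One column per sample (ordered by tumour type, day, batch), one row
#' per Boolean subset; cells are the subset's percentage of CAF+.
#'
#' @param profiles list of [composition_profile()]s.
#' @return List with `matrix` (63 x n), `samples` (column annotation data
#'   frame) and `subsets`.
#' @export
heatmap_matrix <- function(profiles) {
  profiles <- usable_profiles(profiles)
  grp <- profile_groups(profiles)
  ord <- order(grp$tumour_type, grp$day, grp$batch, grp$sample_id)
  mat <- t(100 * profile_matrix(profiles))[, ord, drop = FALSE]
  colnames(mat) <- grp$sample_id[ord]
  list(matrix = mat, samples = grp[ord, ],
       subsets = enumerate_subsets(caf_markers()))
}

#' Pie-and-arc data for a group of samples
#'
#' The SPICE-style view: 63 pie slices (group mean subset fractions of
#' CAF+) and six marker arcs, each covering exactly the slices whose
#' subset contains that marker; an arc's total equals the group's mean
#' per-marker fraction of CAF+.
#'
#' @param profiles list of [composition_profile()]s belonging to one
#'   group.
#' @return List with `slices` (63 mean fractions) and `arcs` (per marker:
#'   covered subset indices and the arc total).
#' @export
pie_arc_data <- function(profiles) {
  profiles <- usable_profiles(profiles)
  if (length(profiles) == 0)
    abort2("no usable profiles in group", class = "composition_error")
  subsets <- enumerate_subsets(caf_markers())
  slices <- colMeans(profile_matrix(profiles))
  arcs <- lapply(caf_markers(), function(m) {
    covered <- subsets$index[subsets[[m]]]
    list(marker = m, subsets = covered,
         total = sum(slices[covered]))
  })
  names(arcs) <- caf_markers()
  list(slices = slices, arcs = arcs)
}

#' Export composition profiles as a flat table
#'
#' One row per sample: metadata, summary percentages, and the 63 subset
#' percentages of CAF+ (columns `S1` to `S63` in binary-index order,
#' labels in the attached `subsets` attribute).
#'
#' @param profiles list of [composition_profile()]s.
#' @return Data frame, one row per sample.
#' @export
composition_table <- function(profiles) {
  grp <- profile_groups(profiles)
  mat <- do.call(rbind, lapply(profiles, function(p)
    100 * p$subset_fractions))
  colnames(mat) <- sprintf("S%d", 1:63)
  out <- cbind(grp,
               data.frame(
                 n_caf_pos = vapply(profiles, function(p)
                   p$n_caf_pos, 1),
                 caf_pos_of_lin_neg = 100 * vapply(profiles, function(p)
                   p$caf_pos_of_lin_neg, 1),
                 lin_neg_of_live = 100 * vapply(profiles, function(p)
                   p$lin_neg_of_live, 1)),
               as.data.frame(mat))
  marker_mat <- do.call(rbind, lapply(profiles, function(p)
    100 * p$per_marker_of_caf_pos))
  colnames(marker_mat) <- paste0("pct_", caf_markers())
  out <- cbind(out, as.data.frame(marker_mat))
  attr(out, "subsets") <- enumerate_subsets(caf_markers())
  rownames(out) <- NULL
  out
}
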