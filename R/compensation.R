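#' Spillover matrices and compensation
#'
#' Spillover is modelled linearly: the observed row vector of fluorescence
#' signals is the true row vector times the spillover matrix `S`
#' (`rows = source fluorophore`, `columns = detector`, unit diagonal).
#' Compensation inverts that mixing: `compensated = observed %*% solve(S)`.
#' Scatter channels are never touched.
#'
#' @param coefficients square numeric matrix; diagonal must be exactly 1,
#'   off-diagonals in `[0, 1)`.
#' @param channels detector ids, one per row/column.
#' @return An object of class `spillover_matrix`.
#' @export
#' @examples
#' s <- spillover_matrix(matrix(c(1, 0, 0.1, 1), 2), c("FITC-A", "PE-A"))
#' s
spillover_matrix <- function(coefficients, channels) {
  coefficients <- as.matrix(coefficients)
  k <- length(channels)
  if (!all(dim(coefficients) == k))
    abort2("spillover matrix must be ", k, "x", k, " to match channels",
           class = "spillover_error")
  if (any(diag(coefficients) != 1))
    abort2("spillover diagonal must be exactly 1",
           class = "spillover_error")
  off <- coefficients[row(coefficients) != col(coefficients)]
  if (any(off < 0) || any(off >= 1))
    abort2("off-diagonal spillover must lie in [0, 1)",
           class = "spillover_error")
  kappa <- kappa(coefficients, exact = TRUE)
  if (!is.finite(kappa))
    abort2("spillover matrix is singular", class = "spillover_error")
  if (kappa > 1e6)
    warning("spillover matrix is ill-conditioned (condition number ",
            format(kappa, digits = 3), ")")
  dimnames(coefficients) <- list(channels, channels)
  structure(list(coefficients = coefficients,
                 channels = as.character(channels)),
            class = "spillover_matrix")
}

#' @export
print.spillover_matrix <- function(x, ...) {
  cat(sprintf("<spillover_matrix> %d channels\n", length(x$channels)))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Read or write a spillover matrix CSV
#'
#' First row and column carry the channel ids; the diagonal must be 1.
#'
#' @param path file path.
#' @param spill a [spillover_matrix()].
#' @export
read_spillover <- function(path) {
  m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  spillover_matrix(m, colnames(m))
}

#' @rdname read_spillover
#' @export
write_spillover <- function(spill, path) {
  utils::write.csv(as.data.frame(spill$coefficients), path)
  invisible(path)
}

#' Estimate a spillover matrix from single-stain controls
#'
#' For each single-stain control the events are split into positive and
#' negative populations on the control's primary channel by
#' one-dimensional two-means clustering (deterministic initialisation at
#' the 10th and 90th percentiles), mirroring how bead controls carry
#' their own internal negative population. The spillover of fluorophore
#' `i` into detector `j` is the ratio of background-subtracted medians,
#' `(median_j(pos) - median_j(neg)) / (median_i(pos) - median_i(neg))`,
#' clipped into `[0, 1)`; negative estimates are physically impossible
#' and are clipped to 0 with a warning.
#'
#' @param controls named list, fluorophore channel id to [event_table()]
#'   of its single-stain control; one entry per fluorescence channel.
#' @param channels detector ids to estimate over; defaults to the names
#'   of `controls`.
#' @return A [spillover_matrix()].
#' @export
estimate_spillover <- function(controls, channels = names(controls)) {
  if (is.null(names(controls)) || !setequal(names(controls), channels))
    abort2("controls must be a named list covering: ",
           paste(channels, collapse = ", "), class = "compensation_error")
  k <- length(channels)
  s <- diag(k)
  dimnames(s) <- list(channels, channels)
  clipped <- FALSE
  for (ch in channels) {
    tab <- controls[[ch]]
    if (nrow(tab$values) < 1000)
      abort2("control for ", ch, " has fewer than 1000 events",
             class = "compensation_error")
    primary <- tab$values[, ch]
    pos <- two_means_split(primary)
    if (sum(pos) < 50 || sum(!pos) < 50)
      abort2("insufficient positive/negative separation in the ", ch,
             " control", class = "insufficient_separation_error")
    d_primary <- stats::median(primary[pos]) - stats::median(primary[!pos])
    if (d_primary <= 0)
      abort2("insufficient positive/negative separation in the ", ch,
             " control", class = "insufficient_separation_error")
    for (other in setdiff(channels, ch)) {
      v <- tab$values[, other]
      coef <- (stats::median(v[pos]) - stats::median(v[!pos])) / d_primary
      if (coef < 0) clipped <- TRUE
      s[ch, other] <- min(max(coef, 0), 1 - 1e-12)
    }
  }
  if (clipped)
    warning("negative spillover estimate(s) clipped to 0")
  spillover_matrix(s, channels)
}

# 1-D two-means with deterministic init at the 10th/90th percentiles;
# returns membership of the upper cluster
two_means_split <- function(x, max_iter = 100) {
  centers <- stats::quantile(x, c(0.1, 0.9), names = FALSE)
  if (diff(centers) == 0)
    abort2("no separation: constant primary channel",
           class = "insufficient_separation_error")
  for (i in seq_len(max_iter)) {
    upper <- abs(x - centers[2]) < abs(x - centers[1])
    new_centers <- c(mean(x[!upper]), mean(x[upper]))
    if (anyNA(new_centers))
      abort2("degenerate two-means split",
             class = "insufficient_separation_error")
    if (isTRUE(all.equal(new_centers, centers))) break
    centers <- new_centers
  }
  upper
}

#' Apply (or undo) spillover mixing
#'
#' `apply_compensation` multiplies the fluorescence block of the event
#' matrix by the inverse spillover matrix and flags the table, refusing
#' to compensate twice. `mix_signals` is the forward operation, used by
#' the generator and in round-trip checks.
#'
#' @param table an [event_table()].
#' @param spill a [spillover_matrix()] over the table's fluorescence
#'   detectors.
#' @param allow_uncompensated unused here; gating passes it through.
#' @return The transformed [event_table()].
#' @export
#' @examples
#' p <- default_panel()
#' s <- default_spillover(p)
#' m <- matrix(100, 4, nrow(p), dimnames = list(NULL, p$detector))
#' et <- event_table(m, p)
#' comp <- apply_compensation(mix_signals(et, s), s)
#' max(abs(comp$values - et$values)) < 1e-9
apply_compensation <- function(table, spill) {
  if (table$compensated)
    abort2("table is already compensated", class = "double_comp_error")
  if (!all(spill$channels %in% table$panel$detector))
    abort2("spillover channels missing from the table",
           class = "compensation_error")
  inv <- tryCatch(solve(spill$coefficients),
                  error = function(e) abort2("singular spillover matrix",
                                             class = "compensation_error"))
  table$values[, spill$channels] <-
    table$values[, spill$channels, drop = FALSE] %*% inv
  table$compensated <- TRUE
  table
}

#' @rdname apply_compensation
#' @export
mix_signals <- function(table, spill) {
  table$values[, spill$channels] <-
    table$values[, spill$channels, drop = FALSE] %*% spill$coefficients
  table
}
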