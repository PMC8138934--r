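#' The six CAF markers, in canonical Boolean-gating order
#'
#' Order matters: Boolean subset indices are binary encodings with bit 1 =
#' the first marker in this vector (alpha-smooth-muscle actin), bit 6 = the
#' last (podoplanin). ASCII spellings are used throughout the package
#' (`aSMA`, `FAPa`, `PDGFRa`, `PDGFRb`).
#'
#' @return Character vector of length 6.
#' @export
#' @examples
#' caf_markers()
caf_markers <- function() {
  c("aSMA", "FAPa", "CD26", "PDGFRa", "PDGFRb", "PDPN")
}

channel_roles <- function() {
  c("scatter_area", "scatter_height", "scatter_width",
    "viability", "lineage_dump", "caf_marker", "other")
}

#' Panel configuration: map detectors to roles and CAF markers
#'
#' A panel is a data frame with one row per detector and columns
#' `detector`, `fluorophore`, `role`, `marker`. A valid panel has unique
#' detector names, exactly one `viability` channel, exactly one
#' `lineage_dump` channel and exactly six `caf_marker` channels (one per
#' marker of [caf_markers()]). The marker mapping lives here, not in FCS
#' keywords, because reporter fluorophores (DsRed for aSMA) carry no
#' antibody keyword.
#'
#' @param panel data frame to validate.
#' @return The validated panel, invisibly for `validate_panel`.
#' @export
#' @examples
#' p <- default_panel()
#' subset(p, role == "caf_marker")
default_panel <- function() {
  p <- data.frame(
    detector = c("FSC-A", "FSC-H", "FSC-W", "SSC-A", "SSC-H", "SSC-W",
                 "DsRed-A", "FITC-A", "PE-A", "PE-Cy7-A", "APC-Vio770-A",
                 "APC-A", "BV711-A", "VioBlue-A"),
    fluorophore = c(NA, NA, NA, NA, NA, NA,
                    "DsRed", "FITC", "PE", "PE-Cy7", "APC-Vio770",
                    "APC", "BV711", "Viobility-405/520"),
    role = c("scatter_area", "scatter_height", "scatter_width",
             "scatter_area", "scatter_height", "scatter_width",
             rep("caf_marker", 6), "lineage_dump", "viability"),
    marker = c(rep(NA, 6), caf_markers(), NA, NA),
    stringsAsFactors = FALSE
  )
  validate_panel(p)
  p
}

#' @rdname default_panel
#' @export
validate_panel <- function(panel) {
  req <- c("detector", "fluorophore", "role", "marker")
  if (!is.data.frame(panel) || !all(req %in% names(panel)))
    abort2("panel must be a data frame with columns ",
           paste(req, collapse = ", "), class = "panel_error")
  if (anyDuplicated(panel$detector))
    abort2("duplicate detector names in panel", class = "panel_error")
  if (!all(panel$role %in% channel_roles()))
    abort2("unknown channel role: ",
           paste(setdiff(panel$role, channel_roles()), collapse = ", "),
           class = "panel_error")
  if (sum(panel$role == "viability") != 1)
    abort2("panel must have exactly one viability channel",
           class = "panel_error")
  if (sum(panel$role == "lineage_dump") != 1)
    abort2("panel must have exactly one lineage_dump channel",
           class = "panel_error")
  cm <- panel$marker[panel$role == "caf_marker"]
  if (length(cm) != 6 || !setequal(cm, caf_markers()) || anyDuplicated(cm))
    abort2("panel must have exactly six caf_marker channels covering ",
           paste(caf_markers(), collapse = ", "), class = "panel_error")
  invisible(panel)
}

#' Read or write a panel configuration CSV
#'
#' The file has the four panel columns (`detector`, `fluorophore`, `role`,
#' `marker`); empty cells become `NA`.
#'
#' @param path file path.
#' @param panel a valid panel data frame.
#' @return `read_panel` returns the validated panel.
#' @export
read_panel <- function(path) {
  p <- utils::read.csv(path, stringsAsFactors = FALSE,
                       na.strings = c("", "NA"))
  validate_panel(p)
  p
}

#' @rdname read_panel
#' @export
write_panel <- function(panel, path) {
  validate_panel(panel)
  utils::write.csv(panel, path, row.names = FALSE, na = "")
  invisible(path)
}

# detector name for a role (or a specific marker) in a panel
panel_detector <- function(panel, role, marker = NULL) {
  if (!is.null(marker)) {
    d <- panel$detector[panel$role == "caf_marker" & panel$marker == marker]
  } else {
    d <- panel$detector[panel$role == role]
  }
  if (length(d) == 0)
    abort2("panel has no channel for ", marker %||% role,
           class = "panel_error")
  d
}

# detectors carrying fluorescence (subject to spillover): markers + dump +
# viability, in panel order
fluor_detectors <- function(panel) {
  panel$detector[panel$role %in% c("caf_marker", "lineage_dump", "viability")]
}
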