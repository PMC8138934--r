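#' Event tables: the pipeline's universal currency
#'
#' An `event_table` bundles an events-by-channels numeric matrix with its
#' panel (channel metadata) and sample metadata. Values are stored on the
#' linear scale; no transform is applied on construction or load.
#'
#' @param values numeric matrix, events in rows, one column per panel
#'   detector (column names must equal `panel$detector`).
#' @param panel a valid panel (see [default_panel()]).
#' @param meta a list of sample metadata, see [sample_meta()].
#' @param compensated logical flag; set by [apply_compensation()] to
#'   prevent double compensation.
#' @return An object of class `event_table`.
#' @export
#' @examples
#' p <- default_panel()
#' m <- matrix(0, 5, nrow(p), dimnames = list(NULL, p$detector))
#' et <- event_table(m, p, sample_meta("s1", "4T1", 7, "rep1"))
#' et
event_table <- function(values, panel, meta = list(),
                        compensated = FALSE) {
  validate_panel(panel)
  if (!is.matrix(values) || !is.numeric(values))
    abort2("values must be a numeric matrix", class = "event_table_error")
  if (nrow(values) == 0)
    abort2("event table must contain at least one event",
           class = "event_table_error")
  if (is.null(colnames(values)) ||
      !identical(colnames(values), panel$detector))
    abort2("value columns must match panel detectors in order",
           class = "event_table_error")
  if (anyNA(values))
    abort2("event table must not contain missing values",
           class = "event_table_error")
  structure(list(values = values, panel = panel, meta = meta,
                 compensated = isTRUE(compensated)),
            class = "event_table")
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("<event_table> %d events x %d channels%s\n",
              nrow(x$values), ncol(x$values),
              if (x$compensated) " (compensated)" else ""))
  if (!is.null(x$meta$sample_id))
    cat(sprintf("  sample: %s (%s, day %s, batch %s, %s)\n",
                x$meta$sample_id, x$meta$tumour_type %||% "?",
                x$meta$day %||% "?", x$meta$batch %||% "?",
                x$meta$control_kind %||% "experimental"))
  invisible(x)
}

#' @export
dim.event_table <- function(x) dim(x$values)

# column of the value matrix for a role/marker
channel_values <- function(table, role, marker = NULL) {
  table$values[, panel_detector(table$panel, role, marker)]
}

# replace the kept events, preserving panel/meta/flags
subset_events <- function(table, keep) {
  if (!any(keep))
    abort2("gate removed every event", class = "gating_error")
  table$values <- table$values[keep, , drop = FALSE]
  table
}

#' Sample metadata
#'
#' Describes one acquired tube: experimental sample, FMO control
#' (`control_kind = "fmo:<marker>"`), bead control (`"beads:<fluorophore>"`)
#' or unstained. Healthy samples are day-0 by design.
#'
#' @param sample_id unique sample identifier.
#' @param tumour_type one of `"4T1"`, `"4T07"`, `"healthy"`.
#' @param day collection day, one of 0, 7, 14, 21.
#' @param batch biological repeat identifier.
#' @param control_kind `"experimental"`, `"unstained"`, `"fmo:<marker>"`
#'   or `"beads:<fluorophore>"`.
#' @return A named list of class `sample_meta`.
#' @export
sample_meta <- function(sample_id, tumour_type, day, batch,
                        control_kind = "experimental") {
  if (!tumour_type %in% c("4T1", "4T07", "healthy"))
    abort2("unknown tumour_type: ", tumour_type, class = "meta_error")
  if (!day %in% c(0, 7, 14, 21))
    abort2("day must be one of 0, 7, 14, 21 (got ", day, ")",
           class = "meta_error")
  if (tumour_type == "healthy" && day != 0)
    abort2("healthy samples are day 0 by design", class = "meta_error")
  if (grepl("^fmo:", control_kind)) {
    m <- sub("^fmo:", "", control_kind)
    if (!m %in% caf_markers())
      abort2("FMO control references unknown marker: ", m,
             class = "meta_error")
  } else if (!grepl("^beads:", control_kind) &&
             !control_kind %in% c("experimental", "unstained")) {
    abort2("unknown control_kind: ", control_kind, class = "meta_error")
  }
  structure(list(sample_id = as.character(sample_id),
                 tumour_type = tumour_type, day = as.integer(day),
                 batch = as.character(batch),
                 control_kind = control_kind),
            class = "sample_meta")
}

#' Load a sample sheet CSV
#'
#' Required columns: `sample_id`, `tumour_type`, `day`, `batch`; optional
#' `control_kind` (default experimental) and `path`. Every row is
#' validated; errors name the offending row.
#'
#' @param path CSV file path.
#' @return A list of [sample_meta()] records; file paths, when present,
#'   are attached as the `path` element of each record.
#' @export
load_sample_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "tumour_type", "day", "batch")
  if (nrow(df) == 0)
    abort2("sample sheet is empty", class = "sheet_error")
  if (!all(req %in% names(df)))
    abort2("sample sheet must have columns ", paste(req, collapse = ", "),
           class = "sheet_error")
  if (anyDuplicated(df$sample_id))
    abort2("duplicate sample_id in sample sheet: ",
           paste(unique(df$sample_id[duplicated(df$sample_id)]),
                 collapse = ", "),
           class = "sheet_error")
  lapply(seq_len(nrow(df)), function(i) {
    rec <- tryCatch(
      sample_meta(df$sample_id[i], df$tumour_type[i], df$day[i],
                  df$batch[i],
                  if ("control_kind" %in% names(df))
                    df$control_kind[i] else "experimental"),
      error = function(e) abort2("sample sheet row ", i, ": ",
                                 conditionMessage(e),
                                 class = "sheet_error"))
    if ("path" %in% names(df)) rec$path <- df$path[i]
    rec
  })
}
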