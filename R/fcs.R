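#' Minimal FCS 3.1 reader and writer
#'
#' Flow-cytometry standard files: a fixed ASCII header with segment
#' offsets, a delimited TEXT segment of keyword/value pairs, and a binary
#' DATA segment. This implementation covers the list-mode floating-point
#' layout used by modern instruments: `$MODE L`, `$DATATYPE F` (32-bit
#' float) or `D` (64-bit), little- or big-endian `$BYTEORD`. Values are
#' stored and returned on the linear scale; no display transform is
#' applied.
#'
#' `write_fcs` additionally records the panel roles, sample metadata and
#' compensation flag under `CAFCYTO*` custom keywords, so a round trip
#' through disk reconstructs the full [event_table()]. Foreign files
#' without those keywords need an explicit `panel`.
#'
#' @param path file path.
#' @param panel optional panel to attach when the file carries no
#'   `CAFCYTO` keywords; detectors must match `$PnN` names.
#' @param table an [event_table()].
#' @return `read_fcs` returns an [event_table()]; `write_fcs` returns
#'   `path` invisibly.
#' @export
#' @examples
#' p <- default_panel()
#' m <- matrix(rexp(10 * nrow(p)), 10, nrow(p),
#'             dimnames = list(NULL, p$detector))
#' et <- event_table(m, p, sample_meta("s1", "4T1", 7, "rep1"))
#' f <- tempfile(fileext = ".fcs")
#' write_fcs(et, f)
#' et2 <- read_fcs(f)
#' max(abs(et2$values - et$values)) # single-precision round-trip
read_fcs <- function(path, panel = NULL) {
  if (!file.exists(path))
    abort2("file not found: ", path, class = "fcs_error")
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58, useBytes = TRUE)
  if (nchar(header) < 58)
    abort2("truncated FCS header (offset 0): ", path, class = "fcs_error")
  version <- substr(header, 1, 6)
  if (!version %in% c("FCS2.0", "FCS3.0", "FCS3.1"))
    abort2("unsupported FCS version: ", version, class = "fcs_error")
  off <- suppressWarnings(as.numeric(vapply(0:5, function(i)
    substr(header, 11 + i * 8, 18 + i * 8), "")))
  if (anyNA(off[1:2]))
    abort2("malformed header offsets (offset 10)", class = "fcs_error")
  text_start <- off[1]; text_end <- off[2]

  seek(con, text_start)
  raw_text <- readChar(con, text_end - text_start + 1, useBytes = TRUE)
  kw <- parse_fcs_text(raw_text)

  data_start <- off[3]; data_end <- off[4]
  if (is.na(data_start) || data_start == 0) {
    data_start <- as.numeric(kw[["$BEGINDATA"]])
    data_end <- as.numeric(kw[["$ENDDATA"]])
  }
  n_par <- as.integer(kw[["$PAR"]])
  n_tot <- as.integer(kw[["$TOT"]])
  dtype <- toupper(trimws(kw[["$DATATYPE"]]))
  mode <- toupper(trimws(kw[["$MODE"]] %||% "L"))
  if (mode != "L")
    abort2("unsupported $MODE: ", mode, class = "fcs_error")
  if (!dtype %in% c("F", "D"))
    abort2("unsupported $DATATYPE: ", dtype, class = "fcs_error")
  byteord <- trimws(kw[["$BYTEORD"]] %||% "1,2,3,4")
  endian <- if (startsWith(byteord, "1")) "little" else "big"
  size <- if (dtype == "F") 4L else 8L
  bits <- vapply(seq_len(n_par), function(i)
    as.integer(kw[[sprintf("$P%dB", i)]]), 1L)
  if (!all(bits == size * 8L))
    abort2("inconsistent $PnB for $DATATYPE ", dtype, class = "fcs_error")

  expected <- as.numeric(n_par) * n_tot
  avail <- floor((data_end - data_start + 1) / size)
  if (avail < expected)
    abort2(sprintf(
      "data segment at offset %d holds %d values but header declares %d",
      data_start, avail, expected), class = "fcs_error")
  seek(con, data_start)
  vals <- readBin(con, "numeric", n = expected, size = size,
                  endian = endian)
  if (length(vals) < expected)
    abort2(sprintf("truncated data segment at offset %d", data_start),
           class = "fcs_error")
  m <- matrix(vals, nrow = n_tot, ncol = n_par, byrow = TRUE)
  colnames(m) <- vapply(seq_len(n_par), function(i)
    kw[[sprintf("$P%dN", i)]] %||% sprintf("P%d", i), "")

  pan <- fcs_panel(kw, n_par, colnames(m)) %||% panel
  if (is.null(pan))
    abort2("file carries no panel keywords; supply `panel`",
           class = "fcs_error")
  if (!identical(colnames(m), pan$detector))
    abort2("$PnN names do not match panel detectors", class = "fcs_error")
  meta <- fcs_meta(kw)
  event_table(m, pan, meta,
              compensated = identical(kw[["CAFCYTOCOMP"]], "1"))
}

#' @rdname read_fcs
#' @export
write_fcs <- function(table, path) {
  if (!inherits(table, "event_table"))
    abort2("write_fcs expects an event_table", class = "fcs_error")
  m <- table$values
  if (ncol(m) == 0)
    abort2("cannot write a table with no channels", class = "fcs_error")
  n_par <- ncol(m); n_tot <- nrow(m)
  d <- "/"
  esc <- function(x) gsub(d, paste0(d, d), as.character(x), fixed = TRUE)
  kw <- c("$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
          "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
          "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
          "$NEXTDATA" = "0",
          "$PAR" = as.character(n_par), "$TOT" = as.character(n_tot))
  for (i in seq_len(n_par)) {
    kw[sprintf("$P%dN", i)] <- esc(colnames(m)[i])
    kw[sprintf("$P%dB", i)] <- "32"
    kw[sprintf("$P%dE", i)] <- "0,0"
    kw[sprintf("$P%dR", i)] <- format(max(1, ceiling(max(m[, i]))),
                                      scientific = FALSE)
    fl <- table$panel$fluorophore[i]
    if (!is.na(fl)) kw[sprintf("$P%dS", i)] <- esc(fl)
    kw[sprintf("CAFCYTOP%dROLE", i)] <- table$panel$role[i]
    mk <- table$panel$marker[i]
    if (!is.na(mk)) kw[sprintf("CAFCYTOP%dMARKER", i)] <- mk
  }
  for (f in c("sample_id", "tumour_type", "day", "batch", "control_kind"))
    if (!is.null(table$meta[[f]]))
      kw[paste0("CAFCYTO", toupper(f))] <- esc(table$meta[[f]])
  if (table$compensated) kw["CAFCYTOCOMP"] <- "1"

  # offsets depend on TEXT length; fixed-width offset fields make one
  # pass deterministic
  fmt_off <- function(x) sprintf("%012d", x)
  build_text <- function(b, e) {
    kv <- c(kw, "$BEGINDATA" = fmt_off(b), "$ENDDATA" = fmt_off(e))
    paste0(d, paste0(names(kv), d, unname(kv), d, collapse = ""))
  }
  text_start <- 58
  probe <- build_text(0, 0)
  data_start <- text_start + nchar(probe, type = "bytes")
  data_end <- data_start + 4 * n_par * n_tot - 1
  text <- build_text(data_start, data_end)
  stopifnot(nchar(text, type = "bytes") == nchar(probe, type = "bytes"))
  text_end <- data_start - 1

  hdr_off <- function(x) if (x <= 99999999) sprintf("%8d", x) else
    sprintf("%8d", 0)
  header <- paste0("FCS3.1    ", hdr_off(text_start), hdr_off(text_end),
                   hdr_off(data_start), hdr_off(data_end),
                   sprintf("%8d", 0), sprintf("%8d", 0))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL, useBytes = TRUE)
  writeChar(text, con, eos = NULL, useBytes = TRUE)
  writeBin(as.vector(t(table$values)), con, size = 4, endian = "little")
  invisible(path)
}

# split a delimited TEXT segment into a named list; doubled delimiters
# escape literal delimiter characters
parse_fcs_text <- function(raw_text) {
  d <- substr(raw_text, 1, 1)
  body <- substr(raw_text, 2, nchar(raw_text))
  tok <- strsplit(body, d, fixed = TRUE)[[1]]
  # re-join tokens produced by escaped (doubled) delimiters: an empty
  # token means the delimiter was literal
  out <- character(0); cur <- tok[1] %||% ""
  i <- 2
  while (i <= length(tok)) {
    if (identical(tok[i], "")) {
      cur <- paste0(cur, d, tok[i + 1] %||% "")
      i <- i + 2
    } else {
      out <- c(out, cur); cur <- tok[i]; i <- i + 1
    }
  }
  out <- c(out, cur)
  if (length(out) %% 2 == 1) out <- out[-length(out)]
  keys <- out[seq(1, length(out), by = 2)]
  vals <- out[seq(2, length(out), by = 2)]
  stats::setNames(as.list(vals), toupper(keys))
}

fcs_panel <- function(kw, n_par, detectors) {
  roles <- vapply(seq_len(n_par), function(i)
    kw[[sprintf("CAFCYTOP%dROLE", i)]] %||% NA_character_, "")
  if (anyNA(roles)) return(NULL)
  markers <- vapply(seq_len(n_par), function(i)
    kw[[sprintf("CAFCYTOP%dMARKER", i)]] %||% NA_character_, "")
  fluor <- vapply(seq_len(n_par), function(i)
    kw[[sprintf("$P%dS", i)]] %||% NA_character_, "")
  p <- data.frame(detector = detectors, fluorophore = fluor,
                  role = roles, marker = markers,
                  stringsAsFactors = FALSE)
  validate_panel(p)
  p
}

fcs_meta <- function(kw) {
  g <- function(f) kw[[paste0("CAFCYTO", toupper(f))]]
  if (is.null(g("sample_id"))) return(list())
  sample_meta(g("sample_id"), g("tumour_type"), as.integer(g("day")),
              g("batch"), g("control_kind") %||% "experimental")
}
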