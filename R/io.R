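# On-disk artifacts. The acquisition delivers three files per measurement: a
# pulse-shape binary, a wavelet-coefficient binary and an FCS list-mode file
# with A/H/W parameters. The instrument's true binary layouts are not
# public, so this package defines its own versioned little-endian layouts
# (documented below) and dispatches on the magic tag, leaving room for
# plug-in readers of foreign layouts.
#
# Pulse binary (magic "PLS1"):
#   magic 4 bytes | version int32 | n_channels int32 | n_samples int32 |
#   sampling_rate float64 | n_events int32 | n_label_levels int32 |
#   per level: length int32 + UTF-8 bytes |
#   per event: event_id int32 | timestamp float64 | label_code int32
#              (0 = absent) | truncated int32 | waveform float32 x
#              (n_channels * n_samples), channel-major.
#
# Wavelet binary (magic "WVL1"):
#   magic | version int32 | n_channels int32 | n_coeff int32 | n_events
#   int32 | per event: event_id int32 | coefficients float32 x
#   (n_channels * n_coeff).

.write_header_string <- function(con, s) {
  raw <- charToRaw(enc2utf8(s))
  writeBin(length(raw), con, size = 4, endian = "little")
  writeBin(raw, con)
}

.read_header_string <- function(con) {
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  rawToChar(readBin(con, "raw", n))
}

.read_checked <- function(con, what, n, size, path) {
  v <- readBin(con, what, n, size = size, endian = "little")
  if (length(v) < n) {
    stop("truncated file ", path, " at byte ", seek(con),
         ": expected ", n, " more ", what, " value(s), got ", length(v),
         call. = FALSE)
  }
  v
}

#' Write / read pulse-shape binaries
#'
#' Lossless (at float32 waveform precision) round trip of waveforms,
#' timestamps, event ids and labels. Reading is streamed event by event
#' (constant memory per event); a truncated or unrecognized file raises an
#' explicit format error with the byte offset, never a silent partial read.
#'
#' @param stream a `pulse_stream`.
#' @param path file path.
#' @return `read_pulses` returns a `pulse_stream` (stains are not stored in
#'   the pulse binary).
#' @export
write_pulses <- function(stream, path) {
  stopifnot(inherits(stream, "pulse_stream"))
  opt <- stream$optics
  n <- n_events(stream)
  levels <- sort(unique(stream$label))
  code <- if (length(levels)) match(stream$label, levels) else integer(0)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("PLS1"), con)
  writeBin(c(1L, opt$n_channels, opt$n_samples), con, size = 4, endian = "little")
  writeBin(opt$sampling_rate, con, size = 8, endian = "little")
  writeBin(c(n, length(levels)), con, size = 4, endian = "little")
  for (l in levels) .write_header_string(con, l)
  for (i in seq_len(n)) {
    writeBin(i - 1L, con, size = 4, endian = "little")
    writeBin(stream$timestamp[i], con, size = 8, endian = "little")
    writeBin(c(if (length(code)) code[i] else 0L,
               as.integer(stream$truncated[i])), con, size = 4, endian = "little")
    w <- as.numeric(t(stream$waveforms[i, , ]))
    if (opt$n_channels == 1) w <- as.numeric(stream$waveforms[i, 1, ])
    writeBin(w, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' @rdname write_pulses
#' @export
read_pulses <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4))
  if (magic != "PLS1") {
    stop("unrecognized pulse-file magic '", magic, "' at byte 0 in ", path,
         "; foreign layouts need a plug-in reader", call. = FALSE)
  }
  hdr <- .read_checked(con, "integer", 3, 4, path)
  version <- hdr[1]; n_ch <- hdr[2]; n_s <- hdr[3]
  if (version != 1L) stop("unsupported pulse-file version ", version, call. = FALSE)
  rate <- .read_checked(con, "numeric", 1, 8, path)
  cnt <- .read_checked(con, "integer", 2, 4, path)
  n <- cnt[1]; n_lev <- cnt[2]
  levels <- character(n_lev)
  for (i in seq_len(n_lev)) levels[i] <- .read_header_string(con)
  optics <- optical_config(sampling_rate = rate, window_length = n_s / rate,
                           n_channels = n_ch)
  waveforms <- array(0, dim = c(n, n_ch, n_s),
                     dimnames = list(NULL, optics$channel_names, NULL))
  ts <- numeric(n); lab <- character(n); trunc <- logical(n)
  for (i in seq_len(n)) {
    .read_checked(con, "integer", 1, 4, path)        # event_id
    ts[i] <- .read_checked(con, "numeric", 1, 8, path)
    meta <- .read_checked(con, "integer", 2, 4, path)
    lab[i] <- if (meta[1] > 0) levels[meta[1]] else NA_character_
    trunc[i] <- meta[2] > 0
    w <- .read_checked(con, "numeric", n_ch * n_s, 4, path)
    waveforms[i, , ] <- matrix(w, nrow = n_ch, byrow = TRUE)
  }
  structure(list(waveforms = waveforms, timestamp = ts, label = lab,
                 diameter = rep(NA_real_, n), truncated = trunc,
                 stains = NULL, optics = optics),
            class = "pulse_stream")
}

#' Header of a pulse binary
#'
#' @param path pulse binary path.
#' @return list with `magic`, `version`, `n_channels`, `n_samples`,
#'   `sampling_rate`, `n_events`, and `record_bytes` (waveform bytes per
#'   event record).
#' @export
pulse_header <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4))
  hdr <- .read_checked(con, "integer", 3, 4, path)
  rate <- .read_checked(con, "numeric", 1, 8, path)
  cnt <- .read_checked(con, "integer", 2, 4, path)
  list(magic = magic, version = hdr[1], n_channels = hdr[2],
       n_samples = hdr[3], sampling_rate = rate, n_events = cnt[1],
       record_bytes = hdr[2] * hdr[3] * 4L)
}

#' Write / read wavelet-coefficient binaries
#'
#' @param coeffs n x (n_channels * n_coeff) matrix, columns grouped by
#'   channel as produced by [wavelet_features()].
#' @param path file path.
#' @param n_channels number of channels the columns are grouped into.
#' @return `read_coeffs` returns the coefficient matrix (float32 precision)
#'   with an `n_channels` attribute.
#' @export
write_coeffs <- function(coeffs, path, n_channels) {
  stopifnot(is.matrix(coeffs), ncol(coeffs) %% n_channels == 0)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("WVL1"), con)
  writeBin(c(1L, as.integer(n_channels),
             as.integer(ncol(coeffs) / n_channels), nrow(coeffs)),
           con, size = 4, endian = "little")
  .write_header_string(con, paste(colnames(coeffs), collapse = "\t"))
  for (i in seq_len(nrow(coeffs))) {
    writeBin(i - 1L, con, size = 4, endian = "little")
    writeBin(as.numeric(coeffs[i, ]), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' @rdname write_coeffs
#' @export
read_coeffs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4))
  if (magic != "WVL1") {
    stop("unrecognized coefficient-file magic '", magic, "' at byte 0 in ",
         path, call. = FALSE)
  }
  hdr <- .read_checked(con, "integer", 4, 4, path)
  if (hdr[1] != 1L) stop("unsupported coefficient-file version", call. = FALSE)
  n_ch <- hdr[2]; n_co <- hdr[3]; n <- hdr[4]
  cn <- strsplit(.read_header_string(con), "\t", fixed = TRUE)[[1]]
  out <- matrix(0, n, n_ch * n_co)
  if (length(cn) == ncol(out)) colnames(out) <- cn
  for (i in seq_len(n)) {
    .read_checked(con, "integer", 1, 4, path)
    out[i, ] <- .read_checked(con, "numeric", n_ch * n_co, 4, path)
  }
  attr(out, "n_channels") <- n_ch
  out
}

# ---------------------------------------------------------------------------
# FCS 3.0/3.1 list mode

.fcs_pad <- function(x, width = 8) formatC(x, width = width, flag = " ")

#' Write an FCS 3.1 list-mode file
#'
#' Standard-conforming minimal FCS 3.1: float32 little-endian list-mode DATA
#' ($DATATYPE F, $MODE L, $BYTEORD 1,2,3,4), one parameter per column with
#' $PnN set to the column name, $PnB 32, $PnE 0,0. Up to 99 parameters.
#'
#' @param data numeric matrix or data.frame, events in rows; column names
#'   become the $PnN short names (conventionally `<channel>-A/-H/-W`).
#' @param path file path.
#' @return invisibly, the path.
#' @export
write_fcs <- function(data, path) {
  data <- as.matrix(data)
  n <- nrow(data); p <- ncol(data)
  if (p < 1 || p > 99) stop("write_fcs: need 1..99 parameters", call. = FALSE)
  if (is.null(colnames(data))) colnames(data) <- paste0("P", seq_len(p))
  if (any(grepl("/", colnames(data), fixed = TRUE))) {
    stop("write_fcs: parameter names must not contain the delimiter '/'",
         call. = FALSE)
  }
  rng <- function(v) if (length(v) && max(v, na.rm = TRUE) > 0)
    format(ceiling(max(v, na.rm = TRUE)) + 1) else "1024"
  kw <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
          "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
          "$BEGINDATA", "%BD%", "$ENDDATA", "%ED%",
          "$BYTEORD", "1,2,3,4", "$DATATYPE", "F", "$MODE", "L",
          "$NEXTDATA", "0",
          "$PAR", format(p), "$TOT", format(n))
  for (j in seq_len(p)) {
    kw <- c(kw, sprintf("$P%dN", j), colnames(data)[j],
            sprintf("$P%dB", j), "32", sprintf("$P%dE", j), "0,0",
            sprintf("$P%dR", j), rng(data[, j]))
  }
  text <- paste0("/", paste(kw, collapse = "/"), "/")
  # fixed-width offsets keep the TEXT length independent of their values
  text_start <- 58L
  text_len <- nchar(text) + 2L * (12L - 4L)  # both placeholders grow 4 -> 12
  data_start <- text_start + text_len
  data_len <- 4L * n * p
  data_end <- if (data_len > 0) data_start + data_len - 1L else 0L
  text_final <- sub("%BD%", sprintf("%012d", if (data_len > 0) data_start else 0L),
                    text, fixed = TRUE)
  text_final <- sub("%ED%", sprintf("%012d", data_end), text_final, fixed = TRUE)
  stopifnot(nchar(text_final) == text_len)
  header <- paste0("FCS3.1    ",
                   .fcs_pad(text_start), .fcs_pad(text_start + text_len - 1L),
                   .fcs_pad(if (data_len > 0 && data_end <= 99999999) data_start else 0L),
                   .fcs_pad(if (data_len > 0 && data_end <= 99999999) data_end else 0L),
                   .fcs_pad(0), .fcs_pad(0))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(text_final), con)
  if (data_len > 0) {
    writeBin(as.numeric(t(data)), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read an FCS 3.0/3.1 list-mode file
#'
#' Minimal standard-conforming reader: parses the HEADER offsets and the
#' delimited TEXT segment, then decodes float32/float64 list-mode DATA in
#' either byte order. Integer data types and analysis segments are out of
#' scope.
#'
#' @param path file path.
#' @return list with `data` (n x p matrix, columns named from $PnN),
#'   `keywords` (named character vector), `version`.
#' @export
read_fcs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- rawToChar(readBin(con, "raw", 58))
  version <- trimws(substr(header, 1, 10))
  if (!version %in% c("FCS3.0", "FCS3.1")) {
    stop("read_fcs: unsupported FCS version '", version, "' in ", path,
         call. = FALSE)
  }
  off <- as.numeric(vapply(0:3, function(i)
    substr(header, 11 + 8 * i, 18 + 8 * i), character(1)))
  text_start <- off[1]; text_end <- off[2]
  seek(con, text_start)
  text <- rawToChar(readBin(con, "raw", text_end - text_start + 1))
  delim <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  kw <- parts[seq(2, length(parts), 2)]
  names(kw) <- toupper(trimws(parts[seq(1, length(parts), 2)]))
  data_start <- off[3]; data_end <- off[4]
  if (data_start == 0 && !is.na(kw["$BEGINDATA"])) {
    data_start <- as.numeric(kw[["$BEGINDATA"]])
    data_end <- as.numeric(kw[["$ENDDATA"]])
  }
  p <- as.integer(kw[["$PAR"]]); n <- as.integer(kw[["$TOT"]])
  dtype <- toupper(kw[["$DATATYPE"]])
  if (!dtype %in% c("F", "D")) {
    stop("read_fcs: only $DATATYPE F/D supported, got ", dtype, call. = FALSE)
  }
  size <- if (dtype == "F") 4L else 8L
  endian <- if (startsWith(kw[["$BYTEORD"]], "1")) "little" else "big"
  m <- matrix(0, n, p)
  if (n * p > 0) {
    seek(con, data_start)
    vals <- readBin(con, "numeric", n * p, size = size, endian = endian)
    if (length(vals) < n * p) {
      stop("read_fcs: DATA segment truncated in ", path, call. = FALSE)
    }
    m <- matrix(vals, n, p, byrow = TRUE)
  }
  pn <- vapply(seq_len(p), function(j) {
    v <- kw[paste0("$P", j, "N")]
    if (is.na(v)) paste0("P", j) else unname(v)
  }, character(1))
  colnames(m) <- pn
  list(data = m, keywords = kw, version = version)
}
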