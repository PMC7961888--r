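# Plain-text readers/writers for every on-disk artifact: delimited
# time-series recordings, JSON profiles/tables/configs, line-oriented
# session logs. Comma separated, "." decimal, "#"-prefixed headers —
# greppable and diff-able; counts round-trip bit exactly.

fmt_full <- function(x) formatC(x, format = "g", digits = 17)

#' Write an EMG recording to a delimited text file
#'
#' Header lines (prefixed `#`) carry the format version, sampling rate,
#' units, channel labels and a JSON meta echo (sensor model, seed); the body
#' is one row per sample: `time_s` plus one column per channel. Counts are
#' written as integers (lossless round trip); volts at full precision.
#'
#' @param rec an [emg_recording()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# emgfb-recording v1",
    sprintf("# fs_hz: %s", fmt_full(rec$fs_hz)),
    sprintf("# units: %s", rec$units),
    sprintf("# channels: %s", paste(rec$channels, collapse = ",")),
    sprintf("# meta: %s", as.character(jsonlite::toJSON(rec$meta,
                                                        auto_unbox = TRUE,
                                                        digits = NA)))
  ), con)
  t <- (seq_len(nrow(rec$samples)) - 1) / rec$fs_hz
  body <- if (rec$units == "counts")
    apply(rec$samples, 2, function(x) sprintf("%d", as.integer(round(x))))
  else
    apply(rec$samples, 2, fmt_full)
  body <- matrix(body, nrow = nrow(rec$samples))
  writeLines(paste("time_s", paste(rec$channels, collapse = ","), sep = ","),
             con)
  writeLines(do.call(paste, c(list(fmt_full(t)), asplit(body, 2),
                              sep = ",")), con)
  invisible(path)
}

read_header <- function(lines) {
  hdr <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!startsWith(ln, "#")) return(list(hdr = hdr, body_start = i))
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) hdr[[m[2]]] <- m[3]
  }
  list(hdr = hdr, body_start = length(lines) + 1)
}

#' Read an EMG recording written by [write_recording()]
#'
#' @param path source file.
#' @param expected_fs_hz optional rate from external configuration; on
#'   mismatch a warning is issued and the file header wins.
#' @return an [emg_recording()].
#' @export
read_recording <- function(path, expected_fs_hz = NULL) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^# emgfb-recording", lines[1]))
    stop(sprintf("%s:1: not an emgfb recording file", path))
  h <- read_header(lines)
  for (f in c("fs_hz", "units", "channels"))
    if (is.null(h$hdr[[f]]))
      stop(sprintf("%s: missing header field '%s'", path, f))
  fs <- as.numeric(h$hdr$fs_hz)
  units <- h$hdr$units
  if (!units %in% c("counts", "volts"))
    stop(sprintf("%s: unknown units '%s'", path, units))
  channels <- strsplit(h$hdr$channels, ",")[[1]]
  if (!is.null(expected_fs_hz) && expected_fs_hz != fs)
    warning(sprintf(
      "configured rate %g Hz differs from file header %g Hz; header wins",
      expected_fs_hz, fs))
  meta <- if (is.null(h$hdr$meta)) list() else
    jsonlite::fromJSON(h$hdr$meta, simplifyVector = TRUE)
  i0 <- h$body_start
  cols <- strsplit(lines[i0], ",")[[1]]
  if (!identical(cols, c("time_s", channels)))
    stop(sprintf("%s:%d: column header does not match the %d declared channels",
                 path, i0, length(channels)))
  body <- lines[(i0 + 1):length(lines)]
  parts <- strsplit(body, ",", fixed = TRUE)
  bad <- which(lengths(parts) != length(channels) + 1)
  if (length(bad))
    stop(sprintf("%s:%d: ragged row (%d fields, expected %d)",
                 path, i0 + bad[1], lengths(parts)[bad[1]],
                 length(channels) + 1))
  m <- matrix(as.numeric(unlist(parts)), ncol = length(channels) + 1,
              byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(apply(m, 1, anyNA))[1]
    stop(sprintf("%s:%d: non-numeric value", path, i0 + bad))
  }
  emg_recording(m[, -1, drop = FALSE], fs, channels = channels,
                units = units, meta = meta)
}

#' Write / read a calibration profile (JSON)
#'
#' @param profile a [calibration_profile()].
#' @param path file path.
#' @return `path` invisibly / the profile.
#' @export
write_calibration <- function(profile, path) {
  obj <- c(list(format = "emgfb-calibration v1"), unclass(profile))
  obj$amplitudes <- as.list(obj$amplitudes)   # keep channel names in JSON
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (is.null(obj$format) || !startsWith(obj$format, "emgfb-calibration"))
    stop(sprintf("%s: not a calibration profile", path))
  amps <- unlist(obj$amplitudes)
  if (any(amps <= 0)) stop(sprintf("%s: non-positive amplitude", path))
  structure(list(amplitudes = amps, window_s = obj$window_s,
                 units = obj$units, source = obj$source,
                 created = obj$created),
            class = "calibration_profile")
}

#' Write / read a score table (JSON)
#'
#' Reading re-validates the schema: contiguous bins spanning (0, 1] and
#' outcome probabilities summing to 1 within 1e-9.
#'
#' @param table a [score_table()].
#' @param path file path.
#' @return `path` invisibly / the validated [score_table()].
#' @export
write_score_table <- function(table, path) {
  obj <- list(format = "emgfb-score-table v1",
              bins = lapply(table, function(b)
                list(lo = b$lo, hi = b$hi, points = I(b$points),
                     prob = I(b$prob))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(obj$format) || !startsWith(obj$format, "emgfb-score-table"))
    stop(sprintf("%s: not a score table", path))
  score_table(lapply(obj$bins, function(b)
    list(lo = b$lo, hi = b$hi, points = unlist(b$points),
         prob = unlist(b$prob))))
}

#' Write / read a session log
#'
#' Line-oriented: `#` header (protocol echo, calibration and table ids,
#' seed), then one CSV record per trial. Reading re-checks the cumulative
#' score invariant.
#'
#' @param log a [play_session()] data frame.
#' @param path file path.
#' @param meta named list echoed into the header (e.g. `protocol`,
#'   `calibration`, `table`, `seed`).
#' @return `path` invisibly / the log data frame.
#' @export
write_session_log <- function(log, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# emgfb-session-log v1", con)
  for (nm in names(meta))
    writeLines(sprintf("# %s: %s", nm,
                       if (is.list(meta[[nm]]))
                         as.character(jsonlite::toJSON(meta[[nm]],
                                                       auto_unbox = TRUE,
                                                       digits = NA))
                       else as.character(meta[[nm]])), con)
  writeLines("trial,onset_s,er,ext_mean,flex_mean,points,bin,degenerate,cum_score",
             con)
  writeLines(sprintf("%d,%s,%s,%s,%s,%d,%d,%d,%d",
                     log$trial, fmt_full(log$onset_s), fmt_full(log$er),
                     fmt_full(log$ext_mean), fmt_full(log$flex_mean),
                     log$points, log$bin, as.integer(log$degenerate),
                     log$cum_score), con)
  invisible(path)
}

#' @rdname write_session_log
#' @export
read_session_log <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^# emgfb-session-log", lines[1]))
    stop(sprintf("%s:1: not an emgfb session log", path))
  h <- read_header(lines)
  body <- lines[(h$body_start + 1):length(lines)]
  parts <- strsplit(body, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 9)
  if (length(bad))
    stop(sprintf("%s:%d: ragged record", path, h$body_start + bad[1]))
  m <- matrix(as.numeric(unlist(parts)), ncol = 9, byrow = TRUE)
  log <- data.frame(trial = as.integer(m[, 1]), onset_s = m[, 2],
                    er = m[, 3], ext_mean = m[, 4], flex_mean = m[, 5],
                    points = as.integer(m[, 6]), bin = as.integer(m[, 7]),
                    degenerate = as.logical(m[, 8]),
                    cum_score = as.integer(m[, 9]))
  if (!identical(log$cum_score, cumsum(log$points)))
    stop(sprintf("%s: cumulative-score invariant violated", path))
  class(log) <- c("session_log", "data.frame")
  log
}

#' Write an envelope as delimited text
#'
#' @param env an [emg_envelope()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_envelope <- function(env, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# emgfb-envelope v1",
               sprintf("# fs_hz: %s", fmt_full(env$fs_hz)),
               sprintf("# units: normalized"),
               sprintf("# channels: %s", paste(env$channels, collapse = ","))),
             con)
  t <- (seq_len(nrow(env$samples)) - 1) / env$fs_hz
  body <- matrix(apply(env$samples, 2, fmt_full), nrow = nrow(env$samples))
  writeLines(paste("time_s", paste(env$channels, collapse = ","), sep = ","),
             con)
  writeLines(do.call(paste, c(list(fmt_full(t)), asplit(body, 2),
                              sep = ",")), con)
  invisible(path)
}
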