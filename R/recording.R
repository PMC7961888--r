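#' Multichannel EMG recording container
#'
#' A uniformly sampled multichannel EMG time series. `samples` is an
#' n-by-k numeric matrix with one column per channel; `units` flags whether
#' values are raw ADC counts or volts.
#'
#' @param samples numeric matrix, one column per channel.
#' @param fs_hz sampling rate in Hz (> 0).
#' @param channels character vector of channel labels (default
#'   `c("extensor", "flexor")` for two columns, else `colnames(samples)`).
#' @param units `"counts"` or `"volts"`. Counts must be whole numbers.
#' @param meta free-form provenance list (sensor model echo, seed, ids).
#' @return an object of class `emg_recording`.
#' @export
emg_recording <- function(samples, fs_hz, channels = NULL,
                          units = c("counts", "volts"), meta = list()) {
  units <- match.arg(units)
  samples <- as.matrix(samples)
  if (is.null(channels)) {
    channels <- colnames(samples)
    if (is.null(channels) && ncol(samples) == 2) channels <- c("extensor", "flexor")
    if (is.null(channels)) channels <- paste0("ch", seq_len(ncol(samples)))
  }
  if (length(channels) != ncol(samples))
    stop("number of channel labels must match number of sample columns")
  stopifnot_scalar(fs_hz, "fs_hz")
  if (fs_hz <= 0) stop("fs_hz must be positive")
  if (units == "counts" && any(samples != round(samples)))
    stop("counts must be whole numbers")
  colnames(samples) <- channels
  structure(list(samples = samples, fs_hz = fs_hz, channels = channels,
                 units = units, meta = meta),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d samples x %d channels (%s) @ %g Hz, units=%s\n",
              nrow(x$samples), length(x$channels),
              paste(x$channels, collapse = ", "), x$fs_hz, x$units))
  invisible(x)
}

n_samples <- function(rec) nrow(rec$samples)

rec_duration_s <- function(rec) nrow(rec$samples) / rec$fs_hz

get_channel <- function(rec, channel) {
  if (!channel %in% rec$channels)
    stop(sprintf("channel '%s' not present (have: %s)", channel,
                 paste(rec$channels, collapse = ", ")))
  rec$samples[, channel]
}
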