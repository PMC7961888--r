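# EMG conditioning chain: bandpass with DC rejection, full-wave
# rectification, windowed smoothing, grip-based calibration, normalization.

#' Processing-pipeline configuration
#'
#' @param band_low_hz,band_high_hz bandpass edges in Hz. Defaults 150 and
#'   450: the online analysis band chosen to reject motion artifact and
#'   crosstalk on unfiltered low-cost sensors (a wider 15-450 band gives
#'   equivalent results for these statistics).
#' @param smooth_kind `"hann"` (display envelope), `"boxcar"` (moving
#'   average) or `"none"`.
#' @param smooth_window_s smoothing window length in seconds. Convention:
#'   0.25 s Hann for display/feedback, 1 s boxcar for the isometric
#'   validation analysis.
#' @param mode `"offline"` (zero-phase filtering, centred windows) or
#'   `"streaming"` (causal filtering, trailing windows).
#' @param filter_order Butterworth prototype order (default 4).
#' @param calib_stat calibration statistic over the windowed rectified
#'   activity: `"max"` (peak 250-ms windowed mean, the default) or `"mean"`
#'   (mean during the grip).
#' @param calib_window_s calibration moving-average window (default 0.25 s).
#' @param calib_floor silent-channel rule: calibration fails when a
#'   channel's amplitude is below `calib_floor` times the quietest windowed
#'   level of the same recording (default 3).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(band_low_hz = 150, band_high_hz = 450,
                            smooth_kind = c("hann", "boxcar", "none"),
                            smooth_window_s = 0.25,
                            mode = c("offline", "streaming"),
                            filter_order = 4,
                            calib_stat = c("max", "mean"),
                            calib_window_s = 0.25,
                            calib_floor = 3) {
  smooth_kind <- match.arg(smooth_kind)
  mode <- match.arg(mode)
  calib_stat <- match.arg(calib_stat)
  stopifnot(band_low_hz > 0, band_low_hz < band_high_hz,
            smooth_window_s > 0, calib_window_s > 0, calib_floor >= 1)
  structure(list(band_low_hz = band_low_hz, band_high_hz = band_high_hz,
                 smooth_kind = smooth_kind, smooth_window_s = smooth_window_s,
                 mode = mode, filter_order = filter_order,
                 calib_stat = calib_stat, calib_window_s = calib_window_s,
                 calib_floor = calib_floor),
            class = "pipeline_config")
}

#' Convert a counts recording to volts
#'
#' `volts = counts * supply_v / (2^adc_bits - 1)`, so full scale maps to the
#' supply voltage and the ADC midpoint code to (one LSB below) `supply_v/2`.
#'
#' @param rec an [emg_recording()] in counts.
#' @param model the [sensor_model()] that produced it.
#' @return the recording with samples in volts and the units flag updated.
#' @export
counts_to_volts <- function(rec, model = sensor_model()) {
  if (rec$units != "counts") stop("recording is already in volts")
  rec$samples <- rec$samples * model$supply_v / adc_max_code(model)
  rec$units <- "volts"
  rec
}

band_filter <- function(cfg, fs_hz) {
  if (cfg$band_high_hz >= fs_hz / 2)
    stop("band_high_hz must be below the Nyquist frequency")
  butter_bandpass(cfg$band_low_hz, cfg$band_high_hz, fs_hz,
                  order = cfg$filter_order)
}

#' Bandpass-filter a recording
#'
#' Butterworth bandpass removing the DC offset (including the sensor's
#' supply-midpoint bias) and out-of-band noise. Offline mode filters
#' zero-phase (forward-backward) after removing the channel mean, so a
#' constant input maps exactly to zero and any added offset leaves the
#' output unchanged; streaming mode is strictly causal.
#'
#' @param rec an [emg_recording()] (counts or volts).
#' @param cfg a [pipeline_config()].
#' @return the recording with filtered samples (units label preserved).
#' @export
bandpass <- function(rec, cfg = pipeline_config()) {
  filt <- band_filter(cfg, rec$fs_hz)
  f <- if (cfg$mode == "offline") {
    function(x) filtfilt_fb(filt, x - mean(x))
  } else {
    function(x) iir_filter(filt, x)
  }
  rec$samples <- apply(rec$samples, 2, f)
  rec$units <- if (rec$units == "counts") "counts" else "volts"
  rec$meta$filtered <- c(cfg$band_low_hz, cfg$band_high_hz)
  rec
}

#' Full-wave rectification
#'
#' @param x numeric vector or matrix.
#' @return elementwise absolute value.
#' @export
rectify <- function(x) abs(x)

smooth_window <- function(kind, w) {
  win <- switch(kind,
                boxcar = rep(1, w),
                hann = if (w == 1) 1 else
                  0.5 * (1 - cos(2 * pi * (seq_len(w) - 1) / (w - 1))),
                stop("unknown window kind"))
  win / sum(win)
}

#' Smooth a series with a unity-DC-gain window
#'
#' Convolution with a normalized Hann or boxcar window (weights sum to 1, so
#' a constant series is unchanged). Offline mode centres the window with
#' reflect padding; streaming mode uses a trailing (causal) window with zero
#' initialization. Output length equals input length.
#'
#' @param x numeric vector or matrix (columns smoothed independently).
#' @param cfg a [pipeline_config()]; uses `smooth_kind`, `smooth_window_s`,
#'   `mode`.
#' @param fs_hz sampling rate of `x`.
#' @return smoothed series, same shape as `x`.
#' @export
smooth_emg <- function(x, cfg = pipeline_config(), fs_hz) {
  if (cfg$smooth_kind == "none") return(x)
  w <- max(1L, round(cfg$smooth_window_s * fs_hz))
  one <- function(v) {
    if (w >= length(v)) stop("smoothing window longer than the series")
    win <- smooth_window(cfg$smooth_kind, w)
    if (cfg$mode == "offline") {
      nl <- (w - 1) %/% 2; nr <- w - 1 - nl
      vp <- c(v[(nl + 1):2], v, v[(length(v) - 1):(length(v) - nr)])
      as.numeric(stats::filter(vp, win, sides = 2))[(nl + 1):(nl + length(v))]
    } else {
      vp <- c(rep(0, w - 1), v)
      as.numeric(stats::filter(vp, win, sides = 1))[w:(w + length(v) - 1)]
    }
  }
  if (is.matrix(x)) apply(x, 2, one) else one(x)
}

# Trailing moving average used by calibration (always causal so online and
# offline calibration agree).
moving_avg <- function(v, w) {
  vp <- c(rep(0, w - 1), v)
  as.numeric(stats::filter(vp, rep(1 / w, w), sides = 1))[w:(w + length(v) - 1)]
}

#' Calibrate normalization amplitudes from a reference grip
#'
#' Per channel: bandpass, full-wave rectify, 250-ms moving average, then take
#' the maximum over time (or the mean, per `cfg$calib_stat`). The resulting
#' per-channel amplitude is the denominator that maps grip-level activity to
#' ~1 in the normalized envelope. A channel whose amplitude is less than
#' `calib_floor` times the quietest windowed level in the same recording is
#' considered silent and raises a calibration-failure error naming it.
#'
#' @param rec grip [emg_recording()], at least `calib_window_s` long.
#' @param cfg a [pipeline_config()].
#' @return an object of class `calibration_profile` with fields `amplitudes`
#'   (named), `window_s`, `units`, `source`, `created`.
#' @export
calibrate_grip <- function(rec, cfg = pipeline_config()) {
  w <- round(cfg$calib_window_s * rec$fs_hz)
  if (n_samples(rec) < w)
    stop("recording shorter than the calibration window")
  filt <- bandpass(rec, cfg)
  amps <- numeric(length(rec$channels))
  names(amps) <- rec$channels
  for (ch in rec$channels) {
    ma <- moving_avg(rectify(filt$samples[, ch]), w)
    ma <- ma[-seq_len(w - 1)]            # drop fill-in transient
    amp <- switch(cfg$calib_stat, max = max(ma), mean = mean(ma))
    rest <- min(ma)                      # quietest window ~ rest level
    if (amp < cfg$calib_floor * rest)
      stop(sprintf(
        "calibration failure: channel '%s' shows no activity above baseline (amplitude %.3g < %g x rest level %.3g)",
        ch, amp, cfg$calib_floor, rest))
    amps[ch] <- amp
  }
  structure(list(amplitudes = amps, window_s = cfg$calib_window_s,
                 units = rec$units,
                 source = if (is.null(rec$meta$id)) "" else rec$meta$id,
                 created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
            class = "calibration_profile")
}

#' @export
print.calibration_profile <- function(x, ...) {
  cat("<calibration_profile>",
      paste(sprintf("%s=%.4g", names(x$amplitudes), x$amplitudes),
            collapse = " "),
      sprintf("(window %gs, units %s)\n", x$window_s, x$units))
  invisible(x)
}

#' Normalize a rectified series by a calibration amplitude
#'
#' Elementwise division by the channel's calibration amplitude. Values above
#' 1 are preserved (activity beyond the reference grip is informative and
#' clipping would bias the extensor ratio).
#'
#' @param x numeric vector (rectified filtered activity).
#' @param profile a [calibration_profile()].
#' @param channel channel label to take the amplitude from.
#' @return normalized numeric vector.
#' @export
normalize_emg <- function(x, profile, channel) {
  if (!channel %in% names(profile$amplitudes))
    stop(sprintf("channel '%s' not in calibration profile (have: %s)",
                 channel, paste(names(profile$amplitudes), collapse = ", ")))
  x / profile$amplitudes[[channel]]
}

#' Run the full conditioning chain on a recording
#'
#' bandpass -> rectify -> normalize -> smooth, producing the normalized
#' activation envelope used for feedback: ~0 at rest, ~1 at reference-grip
#' amplitude.
#'
#' @param rec an [emg_recording()] in the same units the profile was
#'   computed in.
#' @param profile a [calibration_profile()].
#' @param cfg a [pipeline_config()].
#' @return an object of class `emg_envelope` with fields `fs_hz`, `samples`
#'   (matrix), `channels`, `config`.
#' @export
process_emg <- function(rec, profile, cfg = pipeline_config()) {
  if (!is.null(profile$units) && !identical(profile$units, rec$units))
    warning(sprintf("profile computed on %s but recording is in %s",
                    profile$units, rec$units))
  filt <- bandpass(rec, cfg)
  out <- filt$samples
  for (ch in rec$channels)
    out[, ch] <- normalize_emg(rectify(out[, ch]), profile, ch)
  out <- smooth_emg(out, cfg, rec$fs_hz)
  structure(list(fs_hz = rec$fs_hz, samples = out, channels = rec$channels,
                 config = cfg),
            class = "emg_envelope")
}

#' @export
print.emg_envelope <- function(x, ...) {
  cat(sprintf("<emg_envelope> %d samples x %d channels @ %g Hz\n",
              nrow(x$samples), length(x$channels), x$fs_hz))
  invisible(x)
}

#' Streaming processor with chunked state
#'
#' Creates a stateful processor equivalent, sample for sample, to running
#' [process_emg()] in streaming mode on the whole series at once: the IIR
#' filter carries its difference-equation state (trailing inputs and
#' outputs) and the trailing smoother its input tail across chunk
#' boundaries. The first `smooth_window_s` of output is transient
#' (zero-initialized windows).
#'
#' @param channels channel labels.
#' @param profile a [calibration_profile()].
#' @param cfg a [pipeline_config()]; `mode` is forced to `"streaming"`.
#' @param fs_hz sampling rate.
#' @return a function `f(chunk_matrix)` returning the envelope samples for
#'   that chunk.
#' @export
stream_processor <- function(channels, profile, cfg = pipeline_config(),
                             fs_hz = 2000) {
  cfg$mode <- "streaming"
  filt <- band_filter(cfg, fs_hz)
  nb <- length(filt$b) - 1; na <- length(filt$a) - 1
  w <- if (cfg$smooth_kind == "none") 0L else
    max(1L, round(cfg$smooth_window_s * fs_hz))
  st <- lapply(channels, function(ch)
    list(x = rep(0, nb), y = rep(0, na), s = rep(0, max(w - 1, 0))))
  names(st) <- channels
  function(chunk) {
    chunk <- as.matrix(chunk)
    out <- matrix(NA_real_, nrow(chunk), length(channels),
                  dimnames = list(NULL, channels))
    for (j in seq_along(channels)) {
      ch <- channels[j]
      x <- chunk[, j]
      # direct-form-I IIR with carried input/output tails
      xp <- c(st[[ch]]$x, x)
      v <- as.numeric(stats::filter(xp, filt$b, sides = 1))[(nb + 1):length(xp)]
      y <- as.numeric(stats::filter(v, -filt$a[-1], method = "recursive",
                                    init = rev(st[[ch]]$y)))
      st[[ch]]$x <<- xp[(length(xp) - nb + 1):length(xp)]
      st[[ch]]$y <<- y[(length(y) - na + 1):length(y)]
      r <- normalize_emg(rectify(y), profile, ch)
      if (w > 1) {
        win <- smooth_window(cfg$smooth_kind, w)
        rp <- c(st[[ch]]$s, r)
        sm <- as.numeric(stats::filter(rp, win, sides = 1))[w:length(rp)]
        st[[ch]]$s <<- rp[(length(rp) - w + 2):length(rp)]
        r <- sm
      }
      out[, j] <- r
    }
    out
  }
}

#' Downsample an envelope for on-screen display
#'
#' One value per frame: the last envelope sample at or before each frame
#' time. Also returns the heat-map color index `(value - lo) / (hi - lo)`
#' clipped to [0, 1] (low activity maps to blue/0, reference-grip amplitude
#' to red/1 under the default range).
#'
#' @param env an [emg_envelope()].
#' @param fps display refresh rate, frames per second (< `fs_hz`).
#' @param lo,hi dynamic display range for the color mapping (defaults 0, 1).
#' @return data frame with `time_s`, one value column per channel, and one
#'   `<channel>_color` column per channel.
#' @export
downsample_for_display <- function(env, fps = 60, lo = 0, hi = 1) {
  stopifnot(fps > 0, fps < env$fs_hz, hi > lo)
  dur <- nrow(env$samples) / env$fs_hz
  ft <- seq(0, dur - 1 / fps, by = 1 / fps)
  idx <- pmin(floor(ft * env$fs_hz) + 1, nrow(env$samples))
  out <- data.frame(time_s = ft)
  for (ch in env$channels) {
    v <- env$samples[idx, ch]
    out[[ch]] <- v
    out[[paste0(ch, "_color")]] <- clamp((v - lo) / (hi - lo), 0, 1)
  }
  out
}
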