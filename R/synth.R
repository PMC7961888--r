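# Synthetic surface-EMG generation with a low-cost sensor front-end model.
#
# Surface EMG is modelled phenomenologically as amplitude-modulated
# band-limited Gaussian noise: a white process shaped to the physiological
# band, with instantaneous standard deviation set by the muscle activation
# level. The front end mirrors a Myoware-class sensor read by a 3.3 V
# microcontroller ADC: x500 amplification, the amplified signal centred on
# half the supply (about 1.65 V), saturation at the rails, and 12-bit
# quantization at 2000 Hz.

#' Sensor front-end model
#'
#' Parameters of the acquisition chain applied to the (pre-gain,
#' electrode-referred) synthetic EMG. Defaults follow the low-cost device:
#' 500 V/V amplification, 3.3 V supply (so a ~1.65 V midpoint offset),
#' 12-bit ADC, 2000 Hz sampling.
#'
#' @param gain amplification, V/V (> 0).
#' @param supply_v supply voltage in volts (> 0); the offset is `supply_v/2`.
#' @param adc_bits ADC resolution in bits (>= 1).
#' @param fs_hz sampling rate in Hz; must exceed twice the upper shaping edge.
#' @param shaping_band length-2 numeric, spectral band (Hz) of the
#'   physiological signal model. Default 20-450 Hz, the conventional surface
#'   EMG energy band.
#' @param baseline_sd_v electrode-referred noise-floor SD in volts (pre-gain).
#'   The hardware noise floor is not characterised by the device datasheet;
#'   20 uV is a realistic surface-recording floor.
#' @param max_emg_sd_v electrode-referred EMG SD at full activation, volts
#'   (pre-gain). 1 mV RMS is a typical strong voluntary contraction.
#' @param crosstalk fraction in [0, 0.5) of each channel's pre-gain signal
#'   added into the other channel (default 0).
#' @return an object of class `sensor_model`.
#' @export
sensor_model <- function(gain = 500, supply_v = 3.3, adc_bits = 12,
                         fs_hz = 2000, shaping_band = c(20, 450),
                         baseline_sd_v = 20e-6, max_emg_sd_v = 1e-3,
                         crosstalk = 0) {
  stopifnot(gain > 0, supply_v > 0, adc_bits >= 1,
            length(shaping_band) == 2, shaping_band[1] > 0,
            shaping_band[1] < shaping_band[2],
            fs_hz > 2 * shaping_band[2],
            baseline_sd_v >= 0, max_emg_sd_v >= 0,
            crosstalk >= 0, crosstalk < 0.5)
  structure(list(gain = gain, supply_v = supply_v,
                 adc_bits = as.integer(adc_bits), fs_hz = fs_hz,
                 shaping_band = shaping_band, baseline_sd_v = baseline_sd_v,
                 max_emg_sd_v = max_emg_sd_v, crosstalk = crosstalk),
            class = "sensor_model")
}

adc_max_code <- function(model) 2L^model$adc_bits - 1L

#' Volitional activation script
#'
#' Describes piecewise-constant target activation levels per channel, with
#' linear transitions of width `rise_s` starting at each level change. Stands
#' in for the participant's volitional drive.
#'
#' @param duration_s total length in seconds.
#' @param segments data frame with columns `channel`, `start_s`, `end_s`,
#'   `level` (level in [0, 1]); may have zero rows.
#' @param rise_s transition time in seconds (default 0.05).
#' @return an object of class `activation_script`.
#' @export
activation_script <- function(duration_s, segments = NULL, rise_s = 0.05) {
  if (is.null(segments))
    segments <- data.frame(channel = character(), start_s = numeric(),
                           end_s = numeric(), level = numeric())
  stopifnot(duration_s > 0, rise_s >= 0)
  stopifnot(all(c("channel", "start_s", "end_s", "level") %in% names(segments)))
  if (nrow(segments)) {
    if (any(segments$start_s < 0) || any(segments$end_s > duration_s))
      stop("segments must lie within [0, duration_s]")
    if (any(segments$end_s <= segments$start_s))
      stop("segment end must be after start")
    if (any(segments$level < 0 | segments$level > 1))
      stop("levels must lie in [0, 1]")
    for (ch in unique(segments$channel)) {
      s <- segments[segments$channel == ch, ]
      s <- s[order(s$start_s), ]
      if (nrow(s) > 1 && any(s$start_s[-1] < s$end_s[-nrow(s)]))
        stop(sprintf("overlapping segments on channel '%s'", ch))
    }
  }
  structure(list(duration_s = duration_s, segments = segments,
                 rise_s = rise_s), class = "activation_script")
}

#' Build per-channel activation traces from a script
#'
#' Samples the script at `fs_hz`: level is exact inside a segment once the
#' `rise_s`-wide linear transition from the previous level completes; outside
#' segments the level is 0 (reached `rise_s` after the segment end).
#'
#' @param script an [activation_script()].
#' @param fs_hz sampling rate in Hz.
#' @param channels channel labels for the output columns; defaults to
#'   extensor/flexor plus any channels named in the script.
#' @return numeric matrix in [0, 1], `round(duration_s * fs_hz)` rows.
#' @export
build_envelope <- function(script, fs_hz,
                           channels = union(c("extensor", "flexor"),
                                            unique(script$segments$channel))) {
  stopifnot(inherits(script, "activation_script"), fs_hz > 0)
  n <- round(script$duration_s * fs_hz)
  t <- (seq_len(n) - 1) / fs_hz
  out <- matrix(0, n, length(channels), dimnames = list(NULL, channels))
  rise <- script$rise_s
  for (ch in channels) {
    s <- script$segments[script$segments$channel == ch, , drop = FALSE]
    if (!nrow(s)) next
    s <- s[order(s$start_s), ]
    y <- numeric(n)
    for (i in seq_len(nrow(s))) {
      inside <- t >= s$start_s[i] & t < s$end_s[i]
      y[inside] <- s$level[i]
      if (rise > 0) {
        up <- t >= s$start_s[i] & t < s$start_s[i] + rise
        y[up] <- s$level[i] * (t[up] - s$start_s[i]) / rise
        dn <- t >= s$end_s[i] & t < s$end_s[i] + rise
        y[dn] <- s$level[i] * (1 - (t[dn] - s$end_s[i]) / rise)
      }
    }
    out[, ch] <- y
  }
  out
}

# Unit-variance band-limited Gaussian noise: white noise through the shaping
# bandpass, rescaled by the filter's theoretical output SD (impulse-response
# energy), so the stationary SD is exactly 1. Order 6 keeps >95% of the
# spectral power strictly inside the shaping band.
shaped_noise <- function(n, model) {
  filt <- butter_bandpass(model$shaping_band[1], model$shaping_band[2],
                          model$fs_hz, order = 6)
  h <- iir_filter(filt, c(1, rep(0, 4095)))
  g <- sqrt(sum(h^2))
  iir_filter(filt, stats::rnorm(n)) / g
}

#' Synthesize a raw EMG recording from activation traces
#'
#' Per channel: band-limited unit-variance Gaussian noise is scaled
#' sample-wise by `baseline_sd_v + level * max_emg_sd_v` (volts, pre-gain),
#' cross-mixed by `crosstalk`, amplified by `gain`, offset to the supply
#' midpoint `supply_v / 2`, saturated at the rails `[0, supply_v]`, and
#' quantized to `adc_bits`-bit counts. Bit-reproducible for a given seed.
#'
#' @param envelope activation matrix from [build_envelope()] (values in
#'   [0, 1], one column per channel).
#' @param model a [sensor_model()].
#' @param seed integer seed; all randomness derives from it.
#' @return an [emg_recording()] in counts.
#' @export
synthesize_emg <- function(envelope, model = sensor_model(), seed = 1L) {
  envelope <- as.matrix(envelope)
  n <- nrow(envelope); k <- ncol(envelope)
  pre <- with_seed(seed, {
    vapply(seq_len(k), function(j) {
      sd_v <- model$baseline_sd_v + envelope[, j] * model$max_emg_sd_v
      shaped_noise(n, model) * sd_v
    }, numeric(n))
  })
  pre <- matrix(pre, n, k)
  if (model$crosstalk > 0 && k > 1) {
    mixed <- pre
    for (j in seq_len(k))
      mixed[, j] <- pre[, j] + model$crosstalk * rowSums(pre[, -j, drop = FALSE])
    pre <- mixed
  }
  v <- clamp(pre * model$gain + model$supply_v / 2, 0, model$supply_v)
  counts <- round(v / model$supply_v * adc_max_code(model))
  emg_recording(counts, model$fs_hz,
                channels = colnames(envelope),
                units = "counts",
                meta = list(sensor = unclass(model), seed = seed))
}

#' Force-coupling model
#'
#' First-order linear coupling from muscle activation to grip force:
#' force (fraction of MVC) is a low-pass of the activation traces weighted
#' per channel, plus Gaussian noise, clipped at zero.
#'
#' @param weights named per-channel weights (fraction of MVC per unit
#'   activation); default 0.5 each for extensor/flexor so equal co-activation
#'   at level L produces force L.
#' @param tau_s first-order time constant in seconds (> 0); default 0.1 s,
#'   the order of grip-force electromechanical delay.
#' @param noise_sd additive force noise SD, fraction of MVC (default 0.01).
#' @return an object of class `force_model`.
#' @export
force_model <- function(weights = c(extensor = 0.5, flexor = 0.5),
                        tau_s = 0.1, noise_sd = 0.01) {
  stopifnot(all(weights >= 0), tau_s > 0, noise_sd >= 0)
  structure(list(weights = weights, tau_s = tau_s, noise_sd = noise_sd),
            class = "force_model")
}

#' Synthesize a grip-force trace coupled to activation
#'
#' Exact exponential discretization of the first-order lag: with
#' `a = exp(-dt / tau_s)`, `f[t] = a f[t-1] + (1 - a) drive[t]`, where
#' `drive` is the weighted activation sum. A step of height L therefore
#' reaches `(1 - exp(-1)) L` after exactly `tau_s`.
#'
#' @param envelope activation matrix (columns named as in `fmodel$weights`).
#' @param fmodel a [force_model()].
#' @param fs_hz sampling rate of the envelope, Hz.
#' @param seed integer seed for the additive noise.
#' @return numeric force vector, fraction of MVC, nonnegative.
#' @export
synthesize_force <- function(envelope, fmodel = force_model(), fs_hz = 2000,
                             seed = 1L) {
  envelope <- as.matrix(envelope)
  w <- fmodel$weights
  use <- intersect(names(w), colnames(envelope))
  if (length(use) == 0) stop("no envelope channel matches the force weights")
  drive <- as.numeric(envelope[, use, drop = FALSE] %*% w[use])
  a <- exp(-1 / (fs_hz * fmodel$tau_s))
  f <- as.numeric(stats::filter((1 - a) * drive, a, method = "recursive"))
  if (fmodel$noise_sd > 0)
    f <- f + with_seed(seed, stats::rnorm(length(f), 0, fmodel$noise_sd))
  pmax(f, 0)
}

#' Simulate a reference-grip calibration recording
#'
#' Both channels co-activate at `grip_level` for `duration_s` (default the
#' 3-s power grip used for calibration), flanked by rest padding. Suitable
#' input for [calibrate_grip()].
#'
#' @param model a [sensor_model()].
#' @param grip_level activation level of the grip, (0, 1].
#' @param duration_s grip duration in seconds (default 3).
#' @param rest_pad_s rest padding before and after the grip (default 1 s).
#' @param seed integer seed.
#' @return an [emg_recording()] in counts.
#' @export
simulate_grip_recording <- function(model = sensor_model(), grip_level = 1,
                                    duration_s = 3, rest_pad_s = 1,
                                    seed = 1L) {
  stopifnot(grip_level >= 0, grip_level <= 1, duration_s > 0)
  total <- duration_s + 2 * rest_pad_s
  seg <- data.frame(channel = c("extensor", "flexor"),
                    start_s = rest_pad_s, end_s = rest_pad_s + duration_s,
                    level = grip_level)
  if (grip_level == 0) seg <- seg[0, ]
  script <- activation_script(total, seg, rise_s = 0.1)
  env <- build_envelope(script, model$fs_hz)
  rec <- synthesize_emg(env, model, seed)
  rec$meta$kind <- "grip"
  rec$meta$grip_level <- grip_level
  rec
}

#' Simulate a full biofeedback training session
#'
#' Concatenates movement-attempt trials at per-trial extensor/flexor
#' activation levels, with inter-trial and inter-block rests per the training
#' protocol, and returns the raw recording together with the trial onsets.
#'
#' @param protocol a [training_protocol()].
#' @param individuation matrix or data frame with columns `extensor`,
#'   `flexor`: activation levels per trial; rows must equal the protocol's
#'   trial count.
#' @param model a [sensor_model()].
#' @param seed integer seed.
#' @return list with `recording` (counts) and `onsets_s` (numeric vector).
#' @export
simulate_training_session <- function(protocol, individuation,
                                      model = sensor_model(), seed = 1L) {
  individuation <- as.matrix(individuation)
  n_trials <- protocol$blocks * protocol$reps_per_block
  if (nrow(individuation) != n_trials)
    stop(sprintf("individuation has %d rows but the protocol defines %d trials",
                 nrow(individuation), n_trials))
  on <- training_onsets(protocol)
  total <- max(on$onset_s) + protocol$trial_window_s + protocol$inter_trial_rest_s
  seg <- do.call(rbind, lapply(seq_len(n_trials), function(i) {
    data.frame(channel = c("extensor", "flexor"),
               start_s = on$onset_s[i],
               end_s = on$onset_s[i] + protocol$trial_window_s,
               level = c(individuation[i, "extensor"], individuation[i, "flexor"]))
  }))
  seg <- seg[seg$level > 0, , drop = FALSE]
  script <- activation_script(total, seg, rise_s = 0.05)
  env <- build_envelope(script, model$fs_hz)
  rec <- synthesize_emg(env, model, seed)
  rec$meta$kind <- "training_session"
  list(recording = rec, onsets_s = on$onset_s)
}

#' Simulate an isometric ramp-hold validation session
#'
#' Drives both channels with activation proportional to the protocol's force
#' target (ramp to the target fraction of MVC, hold, rest), synthesizes the
#' EMG through the sensor model and the exerted force through the coupling
#' model, as recorded simultaneously in the validation task.
#'
#' @param protocol a [ramp_hold_protocol()].
#' @param model a [sensor_model()].
#' @param fmodel a [force_model()].
#' @param seed integer seed (EMG and force noise use distinct sub-seeds).
#' @return list with `recording` (counts), `force` (fraction of MVC) and the
#'   protocol used.
#' @export
simulate_validation_session <- function(protocol = ramp_hold_protocol(),
                                        model = sensor_model(),
                                        fmodel = force_model(),
                                        seed = 1L) {
  target <- target_trace(protocol, model$fs_hz)
  act <- target / sum(fmodel$weights)   # activation giving force == target
  env <- cbind(extensor = act, flexor = act)
  rec <- synthesize_emg(env, model, child_seed(seed, 1))
  force <- synthesize_force(env, fmodel, model$fs_hz, child_seed(seed, 2))
  rec$meta$kind <- "validation_session"
  list(recording = rec, force = force, protocol = protocol)
}
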