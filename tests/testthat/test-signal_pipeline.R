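# Conditioning chain: units, bandpass with DC rejection, rectification,
# smoothing, calibration, normalization, streaming equivalence, display.

test_that("counts/volts conversion uses the full-scale mapping", {
  rec <- emg_recording(cbind(extensor = c(0L, 2048L, 4095L),
                             flexor = c(0L, 0L, 0L)), 2000)
  v <- counts_to_volts(rec, fx_model)
  expect_equal(v$samples[, "extensor"], c(0, 2048 * 3.3 / 4095, 3.3))
  # midpoint code within one LSB of the 1.65 V supply midpoint
  expect_lt(abs(v$samples[2, "extensor"] - 1.65), 3.3 / 4095)
  expect_error(counts_to_volts(v, fx_model), "volts")
})

test_that("bandpass rejects DC and validates its band", {
  rec <- emg_recording(cbind(extensor = rep(1.65, 4000),
                             flexor = rep(1.65, 4000)), 2000,
                       units = "volts")
  out <- bandpass(rec, fx_cfg)
  expect_lt(abs(mean(out$samples)), 1.65 * 1e-6)
  expect_error(bandpass(rec, pipeline_config(band_high_hz = 1200)),
               "Nyquist")
})

test_that("sinusoid attenuation matches the frequency-response oracle", {
  fs <- 2000
  t <- (0:(8 * fs - 1)) / fs
  filt <- butter_bandpass(150, 450, fs, 4)
  run <- function(f_hz) {
    x <- sin(2 * pi * f_hz * t)
    rec <- emg_recording(cbind(extensor = x, flexor = x), fs,
                         units = "volts")
    y <- bandpass(rec, fx_cfg)$samples[4000:12000, 1]  # skip transients
    sqrt(mean(y^2)) / sqrt(0.5)
  }
  # offline filtering is zero phase, so the observed gain is |H|^2
  expect_equal(run(300), filter_gain(filt, 300, fs)^2, tolerance = 0.05)
  expect_gt(run(300), 0.95)
  expect_lt(run(50), 0.05)
  expect_lt(run(50), filter_gain(filt, 50, fs) * 1.05)
})

test_that("rectification is the elementwise absolute value", {
  expect_equal(rectify(c(-1, 2, -3)), c(1, 2, 3))
  expect_equal(rectify(c(0, 5)), c(0, 5))
  # closed form: mean of a rectified sine is 2/pi times its amplitude
  t <- (0:199999) / 2000
  expect_equal(mean(rectify(3 * sin(2 * pi * 7 * t))), 3 * 2 / pi,
               tolerance = 1e-3)
})

test_that("smoothing windows have unity DC gain and known variance reduction", {
  for (kind in c("hann", "boxcar")) {
    cfg <- pipeline_config(smooth_kind = kind)
    expect_equal(smooth_emg(rep(2.5, 4000), cfg, 2000), rep(2.5, 4000))
  }
  # impulse through a trailing boxcar: flat block of height 1/w
  cfg <- pipeline_config(smooth_kind = "boxcar", smooth_window_s = 0.01,
                         mode = "streaming")
  x <- c(rep(0, 100), 1, rep(0, 199))
  y <- smooth_emg(x, cfg, 2000)
  expect_equal(y[101:120], rep(1 / 20, 20))
  expect_true(all(y[121:300] == 0))
  # white noise variance is reduced by the sum of squared weights
  cfg <- pipeline_config(smooth_kind = "hann", smooth_window_s = 0.025)
  w <- 50
  win <- 0.5 * (1 - cos(2 * pi * (0:(w - 1)) / (w - 1)))
  win <- win / sum(win)
  set.seed(77)
  x <- rnorm(2e5)
  expect_equal(var(smooth_emg(x, cfg, 2000)), sum(win^2),
               tolerance = 0.05)
  expect_error(smooth_emg(rnorm(10), cfg, 2000), "window")
})

test_that("self-normalization of the calibration grip peaks near 1", {
  env <- process_emg(fx_grip, fx_profile, fx_cfg)
  for (ch in env$channels) {
    expect_gte(max(env$samples[, ch]), 0.9)
    expect_lte(max(env$samples[, ch]), 1.1)
  }
  expect_true(all(env$samples >= 0))
  expect_true(all(is.finite(env$samples)))
})

test_that("calibration takes the windowed maximum, not the mean", {
  # two concatenated grips, 0.5 then 1.0: amplitude reflects the 1.0 epoch
  seg <- data.frame(channel = rep(c("extensor", "flexor"), 2),
                    start_s = c(1, 1, 5, 5), end_s = c(4, 4, 8, 8),
                    level = c(0.5, 0.5, 1, 1))
  rec <- synthesize_emg(build_envelope(activation_script(9, seg, 0.1),
                                       fx_model$fs_hz), fx_model, seed = 13)
  prof2 <- calibrate_grip(rec, fx_cfg)
  ref <- calibrate_grip(simulate_grip_recording(fx_model, 1, seed = 13),
                        fx_cfg)
  expect_gt(prof2$amplitudes[["extensor"]],
            0.9 * ref$amplitudes[["extensor"]])
})

test_that("rest-only recordings fail calibration naming the channel", {
  rest <- simulate_grip_recording(fx_model, 0, duration_s = 3, seed = 17)
  expect_error(calibrate_grip(rest, fx_cfg), "calibration failure.*extensor")
})

test_that("calibration amplitude is monotone in grip level at fixed seed", {
  amps <- vapply(c(0.25, 0.5, 1), function(lv)
    calibrate_grip(simulate_grip_recording(fx_model, lv, seed = 19),
                   fx_cfg)$amplitudes[["extensor"]], numeric(1))
  expect_true(all(diff(amps) > 0))
})

test_that("normalization divides by the channel amplitude without clipping", {
  prof <- structure(list(amplitudes = c(extensor = 2, flexor = 4),
                         window_s = 0.25, units = "counts"),
                    class = "calibration_profile")
  expect_equal(normalize_emg(c(2, 2), prof, "extensor"), c(1, 1))
  expect_equal(normalize_emg(c(0, 0), prof, "flexor"), c(0, 0))
  expect_equal(normalize_emg(8, prof, "flexor"), 2)   # above 1, preserved
  expect_error(normalize_emg(1, prof, "biceps"), "biceps")
})

test_that("rest recordings process to a near-zero envelope", {
  rest <- make_level_recording(0.02, 0.02, seed = 23)
  env <- process_emg(rest, fx_profile, fx_cfg)
  expect_lt(mean(env$samples), 0.1)
})

test_that("normalization cancels units: counts and volts pipelines agree", {
  rec_v <- counts_to_volts(fx_grip, fx_model)
  prof_v <- calibrate_grip(rec_v, fx_cfg)
  env_c <- process_emg(fx_grip, fx_profile, fx_cfg)
  env_v <- process_emg(rec_v, prof_v, fx_cfg)
  expect_equal(env_c$samples, env_v$samples, tolerance = 1e-9)
})

test_that("an added offset leaves the offline envelope unchanged", {
  rec <- make_level_recording(0.5, 0.3, seed = 29)
  rec_off <- rec
  rec_off$samples <- rec_off$samples + 100
  env1 <- process_emg(rec, fx_profile, fx_cfg)
  env2 <- process_emg(rec_off, fx_profile, fx_cfg)
  expect_lt(max(abs(env1$samples - env2$samples)) / max(env1$samples), 1e-6)
})

test_that("chunked streaming equals one-shot causal processing exactly", {
  cfgs <- pipeline_config(mode = "streaming")
  prof_s <- calibrate_grip(fx_grip, cfgs)
  rec <- make_level_recording(0.8, 0.4, seed = 37)
  one <- process_emg(rec, prof_s, cfgs)
  sp <- stream_processor(rec$channels, prof_s, cfgs, rec$fs_hz)
  idx <- split(seq_len(nrow(rec$samples)),
               ceiling(seq_len(nrow(rec$samples)) / 777))
  chunked <- do.call(rbind, lapply(idx, function(i)
    sp(rec$samples[i, , drop = FALSE])))
  expect_equal(unname(chunked), unname(one$samples), tolerance = 1e-12)
})

test_that("offline and streaming envelopes agree in windowed means", {
  # compare 250-ms windowed means on the steady epoch after compensating
  # the trailing smoother's known group delay (half the 250-ms window)
  cfgs <- pipeline_config(mode = "streaming")
  prof_s <- calibrate_grip(fx_grip, cfgs)
  rec <- make_level_recording(0.8, 0.8, seed = 41)
  off <- process_emg(rec, fx_profile, fx_cfg)$samples[, 1]
  str <- process_emg(rec, prof_s, cfgs)$samples[, 1]
  w <- 500; lag <- 250
  starts <- seq(3000, 7500 - w, by = w)
  wm_off <- vapply(starts, function(i) mean(off[i:(i + w - 1)]), numeric(1))
  wm_str <- vapply(starts, function(i) mean(str[(i + lag):(i + lag + w - 1)]),
                   numeric(1))
  expect_lt(max(abs(wm_str - wm_off) / wm_off), 0.05)
})

test_that("display downsampling emits one value per frame with color index", {
  env <- make_const_envelope(0.75, 0.25, duration_s = 1)
  d <- downsample_for_display(env, fps = 60, lo = 0, hi = 1)
  expect_equal(nrow(d), 60)
  expect_true(all(d$extensor == 0.75))
  expect_equal(d$extensor_color, rep(0.75, 60))
  # endpoints of the dynamic range map to 0 and 1
  d2 <- downsample_for_display(make_const_envelope(2, 0, duration_s = 0.5),
                               fps = 30, lo = 0, hi = 2)
  expect_true(all(d2$extensor_color == 1))
  expect_true(all(d2$flexor_color == 0))
})
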