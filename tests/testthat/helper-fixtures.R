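# Shared fixtures, built in code once per test run.

fx_model <- sensor_model()

# reference-grip recording and the calibration profiles derived from it
fx_grip <- simulate_grip_recording(fx_model, grip_level = 1, seed = 3)
fx_cfg <- pipeline_config()
fx_profile <- calibrate_grip(fx_grip, fx_cfg)

# a two-channel recording with known activation levels on a steady epoch
make_level_recording <- function(ext, flex, seed, duration_s = 4,
                                 pad_s = 1, model = fx_model) {
  seg <- data.frame(channel = c("extensor", "flexor"),
                    start_s = pad_s, end_s = pad_s + duration_s - 2 * pad_s + 1,
                    level = c(ext, flex))
  seg <- seg[seg$level > 0, , drop = FALSE]
  script <- activation_script(duration_s, seg, rise_s = 0.05)
  synthesize_emg(build_envelope(script, model$fs_hz), model, seed)
}

# constant-valued envelope object (for arithmetic-only tests)
make_const_envelope <- function(ext, flex, duration_s = 4, fs_hz = 2000) {
  n <- round(duration_s * fs_hz)
  structure(list(fs_hz = fs_hz,
                 samples = cbind(extensor = rep(ext, n),
                                 flexor = rep(flex, n)),
                 channels = c("extensor", "flexor"),
                 config = fx_cfg),
            class = "emg_envelope")
}
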