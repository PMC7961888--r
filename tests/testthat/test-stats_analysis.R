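# Hold-phase ER series, paired t, EMG-force regression, session summaries,
# longitudinal trends, exclusion rules.

test_that("hold ER series is computed pointwise within each hold", {
  env <- make_const_envelope(0.3, 0.3, duration_s = 40)
  iv <- data.frame(trial = 1:2, start_s = c(5.5, 22.5), end_s = c(10, 27))
  h <- hold_er_series(env, iv)
  expect_true(all(h$series$er == 0.5))
  expect_equal(h$trial_means, c(0.5, 0.5))

  env$samples[, "flexor"] <- 0
  h2 <- hold_er_series(env, iv)
  expect_true(all(h2$series$er == 1))
  expect_error(hold_er_series(env, iv[0, ]), "no hold intervals")
  expect_error(hold_er_series(env, data.frame(start_s = 39, end_s = 45)),
               "outside")
})

test_that("a simulated validation session yields one mean ER per hold", {
  sess <- simulate_validation_session(seed = 5)
  prof <- calibrate_grip(simulate_grip_recording(seed = 55),
                         pipeline_config(smooth_kind = "boxcar",
                                         smooth_window_s = 1))
  env <- process_emg(sess$recording, prof,
                     pipeline_config(smooth_kind = "boxcar",
                                     smooth_window_s = 1))
  h <- hold_er_series(env, hold_intervals(sess$protocol))
  expect_length(h$trial_means, 12)
  # co-activated isometric holds center the ER distribution near 0.5
  expect_lt(abs(mean(h$trial_means) - 0.5), 0.05)
})

test_that("paired t matches the textbook formula and rejects degeneracy", {
  # differences 1, 2, 3: mean 2, sd 1, t = 2 / (1 / sqrt(3)) = 3.4641
  a <- c(2, 4, 6); b <- c(1, 2, 3)
  r <- paired_t(a, b)
  expect_equal(r$t, 2 * sqrt(3), tolerance = 1e-6)
  expect_equal(r$t, 3.464, tolerance = 1e-3)
  expect_equal(r$df, 2)
  expect_equal(r$p, 2 * stats::pt(-2 * sqrt(3), df = 2), tolerance = 1e-9)

  expect_error(paired_t(a, a), "zero variance")
  expect_error(paired_t(a, a + 5), "zero variance")   # constant shift
  expect_error(paired_t(1:3, 1:4), "equal length")
  expect_error(paired_t(1, 2), "at least 2")
})

test_that("paired t holds its type-I error rate under the null", {
  set.seed(2024)
  n_rep <- 1000
  rej <- vapply(seq_len(n_rep), function(i) {
    a <- rnorm(12, 0.5, 0.1)
    b <- rnorm(12, 0.5, 0.1)
    paired_t(a, b)$p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.035)
  expect_lte(mean(rej), 0.065)
})

test_that("ramp regression reproduces exact and null relationships", {
  n <- 8000
  set.seed(9)
  act <- runif(n, 0, 1)
  env <- make_const_envelope(0, 0)
  env$samples <- cbind(extensor = act, flexor = runif(n))
  iv <- data.frame(start_s = 0, end_s = n / 2000)
  # exact linear coupling: slope recovered, R^2 = 1 (lm warns on the
  # numerically perfect fit; that is the point of the check)
  r <- suppressWarnings(ramp_regression(env, 1.5 * act, iv))
  expect_equal(r$extensor$slope, 1.5, tolerance = 1e-9)
  expect_equal(r$extensor$r2, 1, tolerance = 1e-9)
  # independent channel: R^2 near 0
  expect_lt(r$flexor$r2, 0.01)
  # oracle: brute-force normal equations on the same samples
  x <- act; y <- 1.5 * act + 0.1
  r2 <- suppressWarnings(
    ramp_regression(local({e <- env; e$samples[, 1] <- x; e}), y, iv))
  bhat <- solve(crossprod(cbind(1, x)), crossprod(cbind(1, x), y))
  expect_equal(r2$extensor$intercept, bhat[1], tolerance = 1e-8)
  expect_equal(r2$extensor$slope, bhat[2], tolerance = 1e-8)
  env$samples[, "extensor"] <- 1
  expect_error(ramp_regression(env, y, iv), "constant predictor")
  expect_error(ramp_regression(env, y[1:10], iv), "aligned")
})

test_that("EMG-force R^2 degrades as simulator noise grows", {
  r2_at <- function(noise) {
    fm <- force_model(noise_sd = noise)
    sess <- simulate_validation_session(ramp_hold_protocol(n_trials = 4),
                                        fmodel = fm, seed = 12)
    prof <- calibrate_grip(simulate_grip_recording(seed = 13),
                           pipeline_config(smooth_kind = "boxcar",
                                           smooth_window_s = 1))
    env <- process_emg(sess$recording, prof,
                       pipeline_config(smooth_kind = "boxcar",
                                       smooth_window_s = 1))
    ramp_regression(env, sess$force,
                    ramp_intervals(sess$protocol))$extensor$r2
  }
  clean <- r2_at(0.005)
  noisy <- r2_at(0.2)
  expect_gte(clean, 0.8)
  expect_lt(noisy, clean)
})

test_that("session summaries are trial means with flag propagation", {
  log <- data.frame(er = rep(0.6, 100), ext_mean = 0.5, flex_mean = 0.4,
                    points = 20L, degenerate = FALSE)
  s <- summarize_session(log, 1)
  expect_equal(s$er_mean, 0.6)
  expect_equal(s$score, 2000L)
  expect_equal(s$n_trials, 100L)

  set.seed(3)
  log2 <- data.frame(er = runif(10), ext_mean = runif(10),
                     flex_mean = runif(10), points = sample(0:30, 10, TRUE),
                     degenerate = FALSE)
  s2 <- summarize_session(log2, 2)
  expect_equal(s2$er_mean, sum(log2$er) / 10)       # direct-sum oracle
  log2$degenerate <- TRUE
  expect_true(summarize_session(log2, 3)$degenerate)
  expect_error(summarize_session(log2[0, ], 4), "empty")
  expect_true(summarize_session(NULL, 5, excluded = TRUE,
                                reason = "missing data")$excluded)
})

test_that("longitudinal trend recovers direction and is affine invariant", {
  sm <- do.call(rbind, lapply(1:10, function(i) {
    summarize_session(data.frame(er = 0.5 + 0.01 * i, ext_mean = 0.4,
                                 flex_mean = 0.4, points = 10L,
                                 degenerate = FALSE), i)
  }))
  tr <- longitudinal_trend(sm, "er_mean")
  expect_equal(tr$rho, 1, tolerance = 1e-9)

  # affine rescaling leaves the Pearson correlation unchanged
  sm2 <- sm; sm2$er_mean <- 3 * sm2$er_mean + 0.2
  set.seed(4); sm2$er_mean <- sm2$er_mean + rnorm(10, 0, 0.01)
  t_raw <- longitudinal_trend(sm2, "er_mean")
  sm3 <- sm2; sm3$er_mean <- -2 * sm3$er_mean + 1
  t_scaled <- longitudinal_trend(sm3, "er_mean")
  expect_equal(t_scaled$rho, -t_raw$rho, tolerance = 1e-9)
  expect_equal(t_scaled$p, t_raw$p, tolerance = 1e-9)

  # constant field: degenerate, no correlation defined
  expect_true(longitudinal_trend(sm, "ext_mean")$degenerate)
  expect_error(longitudinal_trend(sm[1:2, ], "er_mean"), "at least 3")
})

test_that("excluded sessions never enter the trend", {
  sm <- do.call(rbind, lapply(1:12, function(i)
    summarize_session(data.frame(er = 0.5 + 0.02 * i, ext_mean = 0.4,
                                 flex_mean = 0.4, points = 10L,
                                 degenerate = FALSE), i)))
  # corrupt two sessions wildly, then exclude them: trend must ignore them
  sm$er_mean[c(3, 7)] <- c(5, -5)
  sm$excluded[c(3, 7)] <- TRUE
  tr <- longitudinal_trend(sm, "er_mean")
  expect_equal(tr$n, 10)
  expect_equal(tr$rho, 1, tolerance = 1e-9)
})

test_that("null drift simulations reject at the nominal rate", {
  set.seed(555)
  rej <- vapply(1:1000, function(i) {
    er <- 0.55 + rnorm(40, 0, 0.05)     # no systematic drift
    sm <- data.frame(session_index = 1:40, er_mean = er, excluded = FALSE)
    longitudinal_trend(sm, "er_mean")$p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.035)
  expect_lte(mean(rej), 0.065)
})

test_that("exclusion rules name their reasons", {
  good <- list(recording = fx_grip, profile = fx_profile, rest_level = 0.02)
  miss <- list(recording = emg_recording(cbind(extensor = 1:10), 2000,
                                         channels = "extensor"),
               profile = fx_profile)
  fail <- list(recording = fx_grip,
               profile = try(stop("silent"), silent = TRUE))
  noisy <- list(recording = fx_grip, profile = fx_profile, rest_level = 0.5)
  fl <- flag_exclusions(list(good, miss, fail, noisy))
  expect_equal(fl$excluded, c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(fl$reason[2:4],
               c("missing data", "calibration failure", "excessive noise"))
})
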