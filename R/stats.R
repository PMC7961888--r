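# Statistical analyses: hold-phase extensor-ratio distributions, paired
# sensor comparison, ramp-phase EMG-force regression, session summaries and
# longitudinal Pearson trends.

#' Extensor-ratio series over hold epochs
#'
#' Pointwise extensor ratio within each hold interval (the per-time-point
#' distributions of the isometric validation figure) plus one mean ER per
#' trial.
#'
#' @param env an [emg_envelope()].
#' @param intervals data frame with `start_s`, `end_s` (and optionally
#'   `trial`), e.g. from the hold rows of [epoch_boundaries()] after
#'   trimming.
#' @param channels length-2 labels, extensor first.
#' @return list with `series` (data frame: `trial`, `time_s`, `er`) and
#'   `trial_means` (numeric, one per interval).
#' @export
hold_er_series <- function(env, intervals,
                           channels = c("extensor", "flexor")) {
  if (!nrow(intervals)) stop("no hold intervals supplied")
  trials <- if ("trial" %in% names(intervals)) intervals$trial
            else seq_len(nrow(intervals))
  ser <- vector("list", nrow(intervals))
  means <- numeric(nrow(intervals))
  for (i in seq_len(nrow(intervals))) {
    i0 <- floor(intervals$start_s[i] * env$fs_hz) + 1
    i1 <- floor(intervals$end_s[i] * env$fs_hz)
    if (i0 < 1 || i1 > nrow(env$samples) || i1 < i0)
      stop(sprintf("interval %d lies outside the recording", i))
    er <- extensor_ratio(env$samples[i0:i1, channels[1]],
                         env$samples[i0:i1, channels[2]])
    ser[[i]] <- data.frame(trial = trials[i],
                           time_s = (i0:i1 - 1) / env$fs_hz,
                           er = as.numeric(er))
    means[i] <- mean(er)
  }
  list(series = do.call(rbind, ser), trial_means = means)
}

#' Paired Student t-test
#'
#' Classical paired t on the differences `a - b`, two-sided p from the t
#' distribution with `n - 1` degrees of freedom. Used to compare per-trial
#' extensor-ratio means acquired with two sensor systems on the same task.
#'
#' @param a,b equal-length numeric vectors of paired per-trial values,
#'   `n >= 2`.
#' @return list with `t`, `df`, `p`, `mean_diff`, `n`.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) stop("paired samples must have equal length")
  if (length(a) < 2) stop("need at least 2 pairs")
  d <- a - b
  if (stats::var(d) == 0)
    stop("degenerate paired t-test: the pairwise differences have zero variance")
  ht <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_diff = mean(d), n = length(a))
}

#' EMG-force regression over ramp epochs
#'
#' Ordinary least squares of force on normalized muscle activity, pooled
#' over the ramp epochs, one fit per channel: the proportion of force
#' variance explained by the activity during force build-up.
#'
#' @param env an [emg_envelope()].
#' @param force force trace aligned to the envelope, fraction of MVC.
#' @param intervals data frame with `start_s`, `end_s` (ramp epochs).
#' @return named list (per channel) of lists `slope`, `intercept`, `r2`, `n`.
#' @export
ramp_regression <- function(env, force, intervals) {
  if (length(force) != nrow(env$samples))
    stop("force trace and envelope are not aligned")
  idx <- unlist(lapply(seq_len(nrow(intervals)), function(i) {
    i0 <- floor(intervals$start_s[i] * env$fs_hz) + 1
    i1 <- floor(intervals$end_s[i] * env$fs_hz)
    if (i0 < 1 || i1 > nrow(env$samples)) stop("interval outside the recording")
    i0:i1
  }))
  out <- lapply(env$channels, function(ch) {
    x <- env$samples[idx, ch]
    if (stats::var(x) == 0)
      stop(sprintf("constant predictor: channel '%s' has no variance over the ramps", ch))
    fit <- stats::lm(y ~ x, data = data.frame(x = x, y = force[idx]))
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r2 = summary(fit)$r.squared, n = length(idx))
  })
  names(out) <- env$channels
  out
}

#' Summarize one training session
#'
#' Arithmetic means of the per-trial normalized extensor activity, flexor
#' activity and extensor ratio, the accumulated game score, and flags:
#' averaging the 100 trials absorbs within-session variability before
#' longitudinal analysis.
#'
#' @param trials a [play_session()] log (or data frame with `er`,
#'   `ext_mean`, `flex_mean`, `points`, `degenerate`).
#' @param index session ordinal.
#' @param excluded logical; if `TRUE` the summary carries no statistics.
#' @param reason exclusion reason string.
#' @return one-row data frame of class `session_summary`.
#' @export
summarize_session <- function(trials, index, excluded = FALSE, reason = "") {
  if (excluded) {
    out <- data.frame(session_index = index, ext_mean = NA_real_,
                      flex_mean = NA_real_, er_mean = NA_real_,
                      score = NA_integer_, n_trials = 0L,
                      degenerate = FALSE, excluded = TRUE, reason = reason)
  } else {
    if (is.null(trials) || !nrow(trials))
      stop("cannot summarize an empty session that is not flagged excluded")
    out <- data.frame(session_index = index,
                      ext_mean = mean(trials$ext_mean),
                      flex_mean = mean(trials$flex_mean),
                      er_mean = mean(trials$er),
                      score = as.integer(sum(trials$points)),
                      n_trials = nrow(trials),
                      degenerate = all(trials$degenerate),
                      excluded = FALSE, reason = "")
  }
  class(out) <- c("session_summary", "data.frame")
  out
}

#' Longitudinal Pearson trend across sessions
#'
#' Pearson correlation between session index and a session-summary field
#' over the non-excluded sessions, with the two-sided p-value from the t
#' transform: the test for systematic change in muscle activity or game
#' performance across training.
#'
#' @param summaries data frame of stacked [summarize_session()] rows.
#' @param field one of `"er_mean"`, `"ext_mean"`, `"flex_mean"`, `"score"`.
#' @return list with `rho`, `p`, `n`, `degenerate` (TRUE with `rho = NA`
#'   when the field is constant).
#' @export
longitudinal_trend <- function(summaries,
                               field = c("er_mean", "ext_mean",
                                         "flex_mean", "score")) {
  field <- match.arg(field)
  use <- summaries[!summaries$excluded, , drop = FALSE]
  if (nrow(use) < 3)
    stop("need at least 3 non-excluded sessions for a trend")
  y <- use[[field]]
  if (stats::var(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = nrow(use),
                degenerate = TRUE))
  ct <- stats::cor.test(use$session_index, y, method = "pearson")
  list(rho = unname(ct$estimate), p = ct$p.value, n = nrow(use),
       degenerate = FALSE)
}

#' Flag sessions for exclusion
#'
#' Operationalizes the exclusion outcome (noisy or incomplete recordings)
#' as explicit rules: a session is excluded when a required channel is
#' missing (`"missing data"`), its calibration failed
#' (`"calibration failure"`), or the rest-epoch envelope mean exceeds
#' `noise_ceiling` (`"excessive noise"`).
#'
#' @param sessions list of per-session lists with fields `recording`
#'   (an [emg_recording()] or `NULL`), `profile` (a [calibration_profile()],
#'   an error/`NULL` when calibration failed), and optionally `rest_level`
#'   (rest-epoch mean of the normalized envelope).
#' @param required_channels channels every recording must carry.
#' @param noise_ceiling rest-level ceiling in normalized units
#'   (default 0.2; a clean rest envelope sits well below 0.1).
#' @return data frame with `session`, `excluded`, `reason`.
#' @export
flag_exclusions <- function(sessions,
                            required_channels = c("extensor", "flexor"),
                            noise_ceiling = 0.2) {
  rows <- lapply(seq_along(sessions), function(i) {
    s <- sessions[[i]]
    reason <- ""
    if (is.null(s$recording) ||
        !all(required_channels %in% s$recording$channels)) {
      reason <- "missing data"
    } else if (is.null(s$profile) || inherits(s$profile, "try-error") ||
               inherits(s$profile, "error")) {
      reason <- "calibration failure"
    } else if (!is.null(s$rest_level) && s$rest_level > noise_ceiling) {
      reason <- "excessive noise"
    }
    data.frame(session = i, excluded = nzchar(reason), reason = reason)
  })
  do.call(rbind, rows)
}
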