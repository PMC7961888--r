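# Timed experimental protocols: the isometric ramp-hold validation task and
# the training-session structure.

#' Isometric ramp-hold validation protocol
#'
#' One trial: a linear force build-up to `target_frac` of maximum voluntary
#' contraction over `ramp_s`, a constant hold for `hold_s`, then `rest_s` of
#' rest — 5 s / 5 s / 7 s at 25% MVC by default, a 17-s sweep, repeated
#' `n_trials` (default 12) times back to back.
#'
#' @param ramp_s,hold_s,rest_s phase durations in seconds (> 0).
#' @param target_frac hold target as a fraction of MVC, (0, 1].
#' @param n_trials number of trials (default 12).
#' @param hold_trim_s initial portion of each hold discarded in analysis to
#'   avoid ramp overshoot (default 0.5 s).
#' @return an object of class `ramp_hold_protocol`.
#' @export
ramp_hold_protocol <- function(ramp_s = 5, hold_s = 5, rest_s = 7,
                               target_frac = 0.25, n_trials = 12,
                               hold_trim_s = 0.5) {
  stopifnot(ramp_s > 0, hold_s > 0, rest_s > 0,
            target_frac > 0, target_frac <= 1, n_trials >= 1,
            hold_trim_s >= 0, hold_trim_s < hold_s)
  structure(list(ramp_s = ramp_s, hold_s = hold_s, rest_s = rest_s,
                 target_frac = target_frac, n_trials = as.integer(n_trials),
                 hold_trim_s = hold_trim_s,
                 trial_s = ramp_s + hold_s + rest_s),
            class = "ramp_hold_protocol")
}

#' Force-target trace for the ramp-hold task
#'
#' Per trial: linear 0 to `target_frac` over the ramp, constant during the
#' hold, 0 during rest; trials concatenated. Continuous except for the drop
#' at rest onset; bounded by `target_frac`.
#'
#' @param p a [ramp_hold_protocol()].
#' @param fs_hz sampling rate in Hz.
#' @return numeric vector of length `round(n_trials * trial_s * fs_hz)`,
#'   fraction of MVC.
#' @export
target_trace <- function(p, fs_hz = 2000) {
  n <- round(p$trial_s * fs_hz)
  t <- (seq_len(n) - 1) / fs_hz
  one <- ifelse(t < p$ramp_s, p$target_frac * t / p$ramp_s,
                ifelse(t < p$ramp_s + p$hold_s, p$target_frac, 0))
  rep(one, p$n_trials)
}

#' Labeled epoch boundaries of a ramp-hold session
#'
#' Half-open `[start_s, end_s)` intervals, three per trial (ramp, hold,
#' rest), tiling the session without gaps: trial `k`'s ramp starts at
#' `k * trial_s`.
#'
#' @param p a [ramp_hold_protocol()].
#' @return data frame with columns `trial`, `phase`, `start_s`, `end_s`.
#' @export
epoch_boundaries <- function(p) {
  k <- rep(seq_len(p$n_trials) - 1, each = 3)
  off <- rep(c(0, p$ramp_s, p$ramp_s + p$hold_s), p$n_trials)
  len <- rep(c(p$ramp_s, p$hold_s, p$rest_s), p$n_trials)
  data.frame(trial = k + 1L,
             phase = rep(c("ramp", "hold", "rest"), p$n_trials),
             start_s = k * p$trial_s + off,
             end_s = k * p$trial_s + off + len)
}

#' Hold and ramp analysis intervals
#'
#' Convenience views of [epoch_boundaries()]: `hold_intervals()` returns the
#' hold epochs with the initial `trim` seconds discarded (ramp-overshoot
#' guard); `ramp_intervals()` the ramp epochs.
#'
#' @param p a [ramp_hold_protocol()].
#' @param trim seconds trimmed from each hold start (default
#'   `p$hold_trim_s`).
#' @return data frame with `trial`, `phase`, `start_s`, `end_s`.
#' @export
hold_intervals <- function(p, trim = p$hold_trim_s) {
  eb <- epoch_boundaries(p)
  h <- eb[eb$phase == "hold", ]
  h$start_s <- h$start_s + trim
  h
}

#' @rdname hold_intervals
#' @export
ramp_intervals <- function(p) {
  eb <- epoch_boundaries(p)
  eb[eb$phase == "ramp", ]
}

#' Training-session protocol
#'
#' Game training structure: `blocks` blocks of `reps_per_block` movement
#' attempts (default 5 x 20 = 100 trials per session), a `trial_window_s`
#' analysis window at each attempt onset, short rests between trials and
#' longer rests between blocks.
#'
#' @param blocks,reps_per_block session structure (defaults 5 and 20).
#' @param trial_window_s analysis/activation window per trial (default 2 s,
#'   the first-2-s trial-mean convention).
#' @param inter_trial_rest_s rest after each trial window (default 3 s).
#' @param inter_block_rest_s rest between blocks (default 60 s; 1-2 min in
#'   practice).
#' @return an object of class `training_protocol`.
#' @export
training_protocol <- function(blocks = 5, reps_per_block = 20,
                              trial_window_s = 2.0, inter_trial_rest_s = 3,
                              inter_block_rest_s = 60) {
  stopifnot(blocks >= 1, reps_per_block >= 1, trial_window_s > 0,
            inter_trial_rest_s >= 0, inter_block_rest_s >= 0)
  structure(list(blocks = as.integer(blocks),
                 reps_per_block = as.integer(reps_per_block),
                 trial_window_s = trial_window_s,
                 inter_trial_rest_s = inter_trial_rest_s,
                 inter_block_rest_s = inter_block_rest_s,
                 n_trials = as.integer(blocks * reps_per_block)),
            class = "training_protocol")
}

#' Trial onsets and block boundaries of a training session
#'
#' @param p a [training_protocol()].
#' @return data frame with `trial`, `block`, `onset_s`; onsets strictly
#'   increasing with gaps of at least `trial_window_s + inter_trial_rest_s`.
#' @export
training_onsets <- function(p) {
  step <- p$trial_window_s + p$inter_trial_rest_s
  onset <- numeric(p$n_trials)
  t <- 0; i <- 0
  for (b in seq_len(p$blocks)) {
    for (r in seq_len(p$reps_per_block)) {
      i <- i + 1
      onset[i] <- t
      t <- t + step
    }
    if (b < p$blocks) t <- t + p$inter_block_rest_s
  }
  data.frame(trial = seq_len(p$n_trials),
             block = rep(seq_len(p$blocks), each = p$reps_per_block),
             onset_s = onset)
}
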