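# Extensor-ratio biofeedback: the antagonist-ratio statistic and the
# probabilistic scoring games built on it.

#' Extensor ratio
#'
#' The antagonist-individuation statistic `ER = ext / (ext + flex)` on mean
#' normalized activities: 1 is pure individuated extension, 0.5 full
#' co-activation, 0 pure flexion. Scale invariant, so normalization units
#' cancel. When the summed activity is below `floor` the ratio is undefined;
#' it is reported as 0.5 (indistinguishable from perfect co-activation) with
#' the `"degenerate"` attribute set.
#'
#' @param ext,flex nonnegative mean normalized activities (vectorized).
#' @param floor degenerate-denominator threshold in normalized units
#'   (default 1e-6).
#' @return numeric in [0, 1], same length as the inputs, with a logical
#'   attribute `"degenerate"`.
#' @examples
#' extensor_ratio(0.4, 0.4)  # 0.5: co-activation
#' extensor_ratio(0.7, 0)    # 1:   individuated extension
#' @export
extensor_ratio <- function(ext, flex, floor = 1e-6) {
  if (any(ext < 0) || any(flex < 0))
    stop("activities must be nonnegative")
  tot <- ext + flex
  degen <- tot < floor
  er <- ifelse(degen, 0.5, ext / ifelse(degen, 1, tot))
  structure(er, degenerate = degen)
}

#' Trial extensor ratio from an envelope pair
#'
#' Channel means over the trial window `[onset, onset + window_s)` (the
#' first-2-s convention by default), then the extensor ratio of the means.
#'
#' @param env an [emg_envelope()] with extensor and flexor channels.
#' @param onset_s trial onset time in seconds.
#' @param window_s averaging window (default 2 s).
#' @param channels length-2 labels, extensor first.
#' @return list with `er`, `ext_mean`, `flex_mean`, `degenerate`.
#' @export
trial_er <- function(env, onset_s, window_s = 2.0,
                     channels = c("extensor", "flexor")) {
  i0 <- floor(onset_s * env$fs_hz) + 1
  i1 <- floor((onset_s + window_s) * env$fs_hz)
  if (i0 < 1 || i1 > nrow(env$samples) || i1 < i0)
    stop("trial window lies outside the recording")
  ext_mean <- mean(env$samples[i0:i1, channels[1]])
  flex_mean <- mean(env$samples[i0:i1, channels[2]])
  er <- extensor_ratio(ext_mean, flex_mean)
  list(er = as.numeric(er), ext_mean = ext_mean, flex_mean = flex_mean,
       degenerate = attr(er, "degenerate"))
}

#' Default SkeeBall score table
#'
#' The published score likelihoods as a function of the extensor ratio:
#' \itemize{
#'   \item 0.9 < ER: 30 points, 100\%
#'   \item 0.6 < ER <= 0.9: 30 points 40\%, 20 points 60\%
#'   \item 0.4 < ER <= 0.6: 20 points 40\%, 10 points 60\%
#'   \item 0.2 < ER <= 0.4: 10 points 20\%, 0 points 80\%
#'   \item ER <= 0.2: 0 points, 100\%
#' }
#' Higher individuation is always reinforced at least as well in
#' expectation (expected points 30, 24, 14, 2, 0 from top to bottom). The
#' published top bin ends at 0.99; ratios in (0.99, 1] are mapped to the top
#' bin since leaving perfect individuation unscored is clearly unintended.
#'
#' @return an object of class `score_table`: list of bins, each with
#'   `lo` (exclusive), `hi` (inclusive), `points`, `prob`.
#' @export
default_score_table <- function() {
  score_table(list(
    list(lo = 0.9, hi = 1.0, points = 30,        prob = 1),
    list(lo = 0.6, hi = 0.9, points = c(30, 20), prob = c(0.4, 0.6)),
    list(lo = 0.4, hi = 0.6, points = c(20, 10), prob = c(0.4, 0.6)),
    list(lo = 0.2, hi = 0.4, points = c(10, 0),  prob = c(0.2, 0.8)),
    list(lo = 0.0, hi = 0.2, points = 0,         prob = 1)
  ))
}

#' Construct and validate a score table
#'
#' Bins are lower-exclusive / upper-inclusive and must partition (0, 1]
#' contiguously from 1 down to 0 (an extensor ratio of exactly 0 falls to
#' the bottom bin). Each bin's outcome probabilities must sum to 1 within
#' 1e-9 and points must be nonnegative.
#'
#' @param bins list of lists with fields `lo`, `hi`, `points`, `prob`.
#' @return an object of class `score_table`.
#' @export
score_table <- function(bins) {
  if (!length(bins)) stop("score table has no bins")
  ord <- order(vapply(bins, function(b) -b$hi, numeric(1)))
  bins <- bins[ord]
  if (abs(bins[[1]]$hi - 1) > 1e-12 || abs(bins[[length(bins)]]$lo) > 1e-12)
    stop("score-table bins must span (0, 1]")
  for (i in seq_along(bins)) {
    b <- bins[[i]]
    if (b$lo >= b$hi) stop(sprintf("bin %d: lo must be below hi", i))
    if (length(b$points) != length(b$prob))
      stop(sprintf("bin %d: points and probabilities differ in length", i))
    if (any(b$points < 0)) stop(sprintf("bin %d: negative points", i))
    if (any(b$prob < 0)) stop(sprintf("bin %d: negative probability", i))
    if (abs(sum(b$prob) - 1) > 1e-9)
      stop(sprintf("bin %d: probabilities sum to %.10f, not 1", i, sum(b$prob)))
    if (i > 1 && abs(bins[[i - 1]]$lo - b$hi) > 1e-12)
      stop("score-table bins must be contiguous")
  }
  structure(bins, class = "score_table")
}

# Index of the bin matching an extensor ratio (lower-exclusive,
# upper-inclusive; er == 0 falls to the bottom bin).
match_bin <- function(er, table) {
  if (er < 0 || er > 1) stop("extensor ratio must lie in [0, 1]")
  if (er == 0) return(length(table))
  for (i in seq_along(table))
    if (er > table[[i]]$lo && er <= table[[i]]$hi) return(i)
  stop("no bin matches the extensor ratio")   # unreachable for a valid table
}

#' Expected points per score-table bin
#'
#' @param table a [score_table()].
#' @return numeric vector of expectations, top bin first.
#' @export
expected_points <- function(table = default_score_table()) {
  vapply(table, function(b) sum(b$points * b$prob), numeric(1))
}

#' Score one or more SkeeBall trials
#'
#' Finds the score-table bin containing each extensor ratio and samples the
#' awarded points from that bin's outcome distribution (deterministic when
#' the bin has a single certain outcome).
#'
#' @param er extensor ratio(s) in [0, 1].
#' @param table a [score_table()].
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return integer vector of awarded points, with attribute `"bin"` giving
#'   the matched bin index (1 = top).
#' @export
score_skeeball <- function(er, table = default_score_table(), seed = NULL) {
  draw <- function() {
    bins <- vapply(er, match_bin, integer(1), table = table)
    pts <- vapply(seq_along(er), function(i) {
      b <- table[[bins[i]]]
      if (length(b$points) == 1) b$points
      else b$points[sample.int(length(b$points), 1, prob = b$prob)]
    }, numeric(1))
    structure(as.integer(pts), bin = bins)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Play a full SkeeBall session over an envelope
#'
#' One trial per onset: the 2-s trial mean activities, the extensor ratio,
#' and the sampled score; the final score is the cumulative sum.
#'
#' @param env an [emg_envelope()].
#' @param onsets_s sorted trial onset times (seconds).
#' @param table a [score_table()].
#' @param seed integer seed for the score draws.
#' @param window_s trial averaging window (default 2 s).
#' @return data frame of class `session_log` with one row per trial:
#'   `trial`, `onset_s`, `er`, `ext_mean`, `flex_mean`, `points`, `bin`,
#'   `degenerate`, `cum_score`.
#' @export
play_session <- function(env, onsets_s, table = default_score_table(),
                         seed = 1L, window_s = 2.0) {
  if (is.unsorted(onsets_s)) stop("trial onsets must be sorted")
  rows <- lapply(onsets_s, function(on) trial_er(env, on, window_s))
  er <- vapply(rows, `[[`, numeric(1), "er")
  pts <- score_skeeball(er, table, seed = seed)
  log <- data.frame(
    trial = seq_along(onsets_s),
    onset_s = as.numeric(onsets_s),
    er = er,
    ext_mean = vapply(rows, `[[`, numeric(1), "ext_mean"),
    flex_mean = vapply(rows, `[[`, numeric(1), "flex_mean"),
    points = as.integer(pts),
    bin = attr(pts, "bin"),
    degenerate = vapply(rows, `[[`, logical(1), "degenerate"),
    cum_score = cumsum(as.integer(pts)))
  class(log) <- c("session_log", "data.frame")
  log
}

#' Blinko board
#'
#' Nine point slots under `n_rows` rows of pegs, labeled
#' 100/500/1000/0/10000/0/1000/500/100 by default: the jackpot sits under
#' the co-activation position, rewarding controlled balance, while strong
#' individuation in either direction earns the outer slots.
#'
#' @param slot_values ordered slot labels (odd count, default 9).
#' @param n_rows peg rows the chip traverses (default 8).
#' @return an object of class `blinko_board`.
#' @export
blinko_board <- function(slot_values = c(100, 500, 1000, 0, 10000,
                                         0, 1000, 500, 100),
                         n_rows = 8) {
  if (length(slot_values) %% 2 == 0)
    stop("a blinko board needs an odd number of slots")
  stopifnot(n_rows >= 0)
  structure(list(slot_values = slot_values, n_rows = as.integer(n_rows),
                 n_slots = length(slot_values)),
            class = "blinko_board")
}

#' Starting slot from the extensor ratio
#'
#' Linear map of ER onto slot indices: 0 to the leftmost (flexion), 1 to the
#' rightmost (extension), 0.5 to the center, nearest-index rounding.
#'
#' @param er extensor ratio in [0, 1].
#' @param board a [blinko_board()].
#' @return 0-based slot index in `0 .. n_slots - 1`.
#' @export
blinko_start_slot <- function(er, board = blinko_board()) {
  if (er < 0 || er > 1) stop("extensor ratio must lie in [0, 1]")
  as.integer(floor(er * (board$n_slots - 1) + 0.5))
}

#' Drop a Blinko chip
#'
#' The chip takes `n_rows` independent half-slot steps left or right with
#' equal probability, reflecting off the board walls, and lands in the slot
#' under its final position.
#'
#' @param start 0-based starting slot index.
#' @param board a [blinko_board()].
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return list with `slot` (0-based landing index) and `points`.
#' @export
blinko_drop <- function(start, board = blinko_board(), seed = NULL) {
  if (start < 0 || start > board$n_slots - 1) stop("invalid start slot")
  run <- function() {
    pos <- start
    hi <- board$n_slots - 1
    if (board$n_rows > 0) {
      steps <- sample(c(-0.5, 0.5), board$n_rows, replace = TRUE)
      for (s in steps) {
        pos <- pos + s
        if (pos < 0) pos <- -pos
        if (pos > hi) pos <- 2 * hi - pos
      }
    }
    slot <- as.integer(floor(pos + 0.5))
    list(slot = slot, points = board$slot_values[slot + 1])
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
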