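# Internal helpers shared across modules.

# Evaluate `expr` under a given RNG seed without disturbing the caller's RNG
# state. All package randomness flows through this; nothing touches the
# global stream permanently.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministic child seed for sub-streams (splittable-by-convention).
# Kept below 2^31 - 1 so it is always a valid R integer seed.
child_seed <- function(seed, k) {
  s <- (abs(as.numeric(seed)) %% 2147483647)
  as.integer(((s + 1) * 69069 + (k %% 65536) * 7919) %% 2147483647)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name))
}
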