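# Internal helpers shared across modules.

# stop() with the calling context suppressed; all user-facing input errors
# go through this so messages are uniform.
abort_input <- function(...) {
  stop(..., call. = FALSE)
}

assert_scalar_number <- function(x, name, positive = FALSE, nonnegative = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_input(sprintf("`%s` must be a single finite number", name))
  }
  if (positive && x <= 0) {
    abort_input(sprintf("`%s` must be > 0 (got %g)", name, x))
  }
  if (nonnegative && x < 0) {
    abort_input(sprintf("`%s` must be >= 0 (got %g)", name, x))
  }
  invisible(x)
}

# Deterministic substream seeds: one global seed fans out to per-generator
# streams so adding a generator does not perturb the draws of another.
# Keeps results within 32-bit integer range.
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offsets <- c(cohort = 101L, recording = 211L, flow = 307L, pipeline = 401L)
  if (!stream %in% names(offsets)) {
    stop("unknown substream: ", stream)
  }
  as.integer((as.numeric(seed) * 7919 + offsets[[stream]]) %% 2147483647)
}

# Evaluate an expression under a local RNG state so callers' streams are
# untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
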