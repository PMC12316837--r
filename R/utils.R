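# Internal helpers: seeded RNG streams that do not disturb the caller's
# random-number state, and small array utilities.

# A self-contained RNG stream. Each draw swaps the stream's state into
# .Random.seed, draws, and restores whatever was there before, so package
# randomness is reproducible from `seed` and invisible to the caller.
local_rng <- function(seed) {
  state <- NULL
  run <- function(fn) {
    old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (is.null(state)) set.seed(seed)
    else assign(".Random.seed", state, envir = globalenv())
    on.exit({
      state <<- get(".Random.seed", envir = globalenv())
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    fn()
  }
  list(
    runif = function(n, min = 0, max = 1) run(function() stats::runif(n, min, max)),
    rnorm = function(n, mean = 0, sd = 1) run(function() stats::rnorm(n, mean, sd)),
    sample = function(x, size = NULL, replace = FALSE)
      run(function() if (is.null(size)) sample(x, replace = replace)
          else sample(x, size, replace))
  )
}

# Deterministic sub-seed derivation (kept within 32-bit integer range).
derive_seed <- function(seed, tag) {
  s <- (as.numeric(seed) %% 2147483647)
  as.integer((s * 1103515245 + 12345 + 97 * as.numeric(tag)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
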