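# A self-contained RNG stream that never disturbs the caller's RNG state:
# the stream's .Random.seed is swapped in around each draw and swapped back.
.seeded_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  with_state <- function(f) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    if (is.null(env$state)) {
      set.seed(seed)
    } else {
      assign(".Random.seed", env$state, envir = globalenv())
    }
    out <- f()
    env$state <- get(".Random.seed", envir = globalenv())
    out
  }
  list(
    shuffle = function(n) with_state(function() sample.int(n)),
    runif = function(n) with_state(function() stats::runif(n)),
    rpois = function(n, lambda) with_state(function() stats::rpois(n, lambda)),
    sample = function(x, size, replace = FALSE, prob = NULL) {
      with_state(function() sample(x, size, replace = replace, prob = prob))
    }
  )
}

# Derive a per-stage child seed from a base seed, stable across stage
# reordering; stays below 2^31.
.derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}
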