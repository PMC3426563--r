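# Private seeded RNG stream: draws are reproducible per seed and never
# disturb (or depend on) the caller's global RNG state.
.local_rng <- function(seed) {
  e <- new.env()
  run <- function(f) {
    function(...) {
      g <- globalenv()
      had <- exists(".Random.seed", envir = g, inherits = FALSE)
      old <- if (had) get(".Random.seed", envir = g) else NULL
      if (is.null(e$state)) {
        set.seed(as.integer(seed))
      } else {
        assign(".Random.seed", e$state, envir = g)
      }
      on.exit({
        e$state <- get(".Random.seed", envir = g)
        if (had) assign(".Random.seed", old, envir = g)
        else rm(".Random.seed", envir = g)
      })
      f(...)
    }
  }
  list(
    norm = run(stats::rnorm),
    unif = run(stats::runif),
    sample = run(function(n, k) sample.int(n, k))
  )
}

# deterministic child seed, kept within 32-bit integer range
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}
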