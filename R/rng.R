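#' Deterministic seed derivation
#'
#' Mixes a master seed with one or more stream indices into a new seed in
#' `[0, 2^31 - 1)`.  Used for counter-based stream splitting: every patch,
#' repetition and fold draws from its own derived stream, so changing the
#' number of items in one cell never reshuffles the randomness of another.
#'
#' @param seed Integer master seed.
#' @param ... Integer stream indices (counters).
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  idx <- c(...)
  h <- as.double(seed %% 2147483647)
  for (k in idx) {
    # affine mix modulo a Mersenne prime; constants are arbitrary odd values
    h <- (h * 48271 + as.double(k %% 2147483647) * 16807 + 12345) %% 2147483647
  }
  as.integer(h)
}

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}
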