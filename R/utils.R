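# internal helpers

# Run `code` with the RNG seeded at `seed`, restoring the caller's RNG state
# afterwards so seeded simulator calls never perturb the global stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      (strict_lower && x <= lower) || (!strict_lower && x < lower) ||
      x > upper) {
    stop(sprintf("'%s' must be a single finite number in the valid range",
                 name), call. = FALSE)
  }
  x
}
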