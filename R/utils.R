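# Typed conditions: every validation failure raised by the package carries a
# subclass of "ponsPET_error" so callers can distinguish failure modes.
petStop <- function(subclass, fmt, ...) {
  stop(structure(
    class = c(paste0("ponsPET_error_", subclass), "ponsPET_error",
              "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

# Cumulative trapezoid of y(t) on an arbitrary ascending grid; returns a
# vector the same length as t with first element 0.
cumTrapz <- function(t, y) {
  n <- length(t)
  if (n == 1L) return(0)
  c(0, cumsum(diff(t) * (y[-1] + y[-n]) / 2))
}

# Restore the caller's RNG state after seeded simulation so simulators do
# not perturb the global stream.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    petStop("seed", "seed must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive per-subject seeds (< 2^31) deterministically from a master seed.
deriveSeeds <- function(masterSeed, n) {
  withSeed(masterSeed, sample.int(.Machine$integer.max, n))
}
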