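# Internal numeric helpers.

# round-half-up to integer (base round() is half-to-even; subsample targets
# and simulated curve heights use the conventional half-up rule)
halfUp <- function(x) floor(x + 0.5)

# Deterministic child seed from a master seed and a stream of indices;
# stays below 2^31 - 1 so it is always a valid R integer seed.
deriveSeed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483629
  for (i in idx) s <- (s * 48271 + as.double(i) * 16807 + 1) %% 2147483629
  as.integer(s)
}

# run expr with a local RNG state (restores the caller's .Random.seed)
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# median as mean of the two middle order statistics for even n (what
# stats::median does for numeric input; kept explicit for clarity)
midMedian <- function(x) stats::median(as.numeric(x))
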