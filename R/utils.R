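# Run `code` with the RNG seeded to `seed` (Mersenne-Twister), restoring
# the caller's RNG state afterwards so library calls never perturb user
# randomness. With seed = NULL the code runs on the current RNG stream.
with_rng <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
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
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  force(code)
}

# Truncated-normal draws by inverse-CDF; lower/upper may be -Inf/Inf.
# Degenerate truncation regions (numerically zero mass) fall back to the
# nearer bound.
rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  out <- qnorm(plo + runif(n) * (phi - plo), mean, sd)
  pmin(pmax(out, lower), upper)
}
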