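# run expr under a temporary RNG seed, restoring the caller's RNG state
with_seed_local <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# derive a child seed, kept within 32-bit integer range
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647L)
}

# truncated-normal draws on [lo, hi] via inverse CDF
rtruncnorm <- function(n, mean, sd, lo = 0, hi = 1) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

# truncated-normal density on [lo, hi]
dtruncnorm <- function(x, mean, sd, lo = 0, hi = 1) {
  z <- pnorm(hi, mean, sd) - pnorm(lo, mean, sd)
  out <- dnorm(x, mean, sd) / z
  out[x < lo | x > hi] <- 0
  out
}

# sliding-window mean of `values` over positions, window = total width in bp
windowed_mean <- function(pos, values, window) {
  half <- window / 2
  lo <- findInterval(pos - half, pos, left.open = TRUE) + 1L
  hi <- findInterval(pos + half, pos)
  cs <- c(0, cumsum(values))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
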