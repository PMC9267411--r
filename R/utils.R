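## derive a reproducible sub-seed (< 2^31) from a master seed and stream id
substreamSeed <- function(seed, id) {
  as.integer((as.double(seed) * 48271 + 7919 * id) %% 2147483647)
}

## round half up (base round() rounds half to even)
roundHalfUp <- function(x) floor(x + 0.5)

## draw from a lognormal with the given arithmetic mean/sd, truncated
rtrunclnorm1 <- function(n, mean, sd, lo = 0, hi = Inf) {
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  meanlog <- log(mean) - sdlog^2 / 2
  x <- stats::rlnorm(n, meanlog, sdlog)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- stats::rlnorm(length(bad), meanlog, sdlog)
    bad <- which(x < lo | x > hi)
  }
  x
}

## draw from a normal truncated to [lo, hi] by redrawing
rtruncnorm1 <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
  }
  x
}

## numeric design-matrix coding: factors/characters become level codes
asNumericCovariate <- function(x) {
  if (is.numeric(x)) x else as.numeric(factor(x))
}
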