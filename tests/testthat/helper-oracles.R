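## Independent brute-force oracles: deliberately written as plain loops over
## the definitions, sharing no code with the package implementation.

oracleStandardize <- function(px, B) {
  out <- px
  for (i in seq_len(nrow(px))) for (j in seq_len(ncol(px))) {
    v <- px[i, j] * 255 / (255 - B)
    out[i, j] <- if (v > 255) 255 else v
  }
  out
}

oracleContinuity <- function(px, trace) {
  tot <- 0
  for (j in 1:50) {
    tot <- tot + if (is.na(trace[j])) 1 else px[trace[j], j]
  }
  tot
}

oracleClarity <- function(px, trace) {
  tot <- 0
  for (j in 1:50) {
    r <- trace[j]
    if (is.na(r)) { tot <- tot + 1; next }
    nbr <- c((r - 3):(r - 1), (r + 1):(r + 3))
    nbr <- nbr[nbr >= 1 & nbr <= 256]
    m <- mean(px[nbr, j])
    if (m < 1) m <- 1
    tot <- tot + px[r, j] / m
  }
  tot / 50
}

oracleArea <- function(ez, rpe) {
  tot <- 0
  for (j in 1:50) {
    if (is.na(ez[j]) || is.na(rpe[j])) next
    d <- rpe[j] - ez[j] - 1
    if (d > 0) tot <- tot + d
  }
  tot
}

## O(n^2) pair-counting AUC with half credit for ties
oracleAucPairs <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

## exact two-sided signed-rank p by looping over all 2^n sign assignments
oracleWilcoxonEnum <- function(x, y) {
  d <- x - y; d <- d[d != 0]; n <- length(d)
  r <- rank(abs(d)); wObs <- sum(r[d > 0])
  ws <- vapply(0:(2^n - 1), function(m)
    sum(r[bitwAnd(m, 2^(0:(n - 1))) > 0]), 0)
  pLe <- mean(ws <= wObs + 1e-9)
  pGe <- mean(ws >= wObs - 1e-9)
  min(1, 2 * min(pLe, pGe))
}

## normal-equations least squares R2 of column j on the others
oracleR2 <- function(X, j) {
  y <- X[, j]; Z <- cbind(1, X[, -j, drop = FALSE])
  beta <- solve(t(Z) %*% Z, t(Z) %*% y)
  1 - sum((y - Z %*% beta)^2) / sum((y - mean(y))^2)
}

## term-by-term evaluation of the weighted penalized logistic loss
oracleLoss <- function(alpha, b, X, y, C, w0, w1) {
  m <- nrow(X)
  tot <- 0
  for (i in seq_len(m)) {
    s <- 1 / (1 + exp(-(sum(alpha * X[i, ]) + b)))
    tot <- tot + w0 * y[i] * log(s) + w1 * (1 - y[i]) * log(1 - s)
  }
  -tot / m + sum(alpha^2) / C
}

randomScan <- function() {
  TrimmedBScan(matrix(sample(0:255, 256 * 50, replace = TRUE), 256, 50),
               vitreousBrightness = runif(1, 0, 80))
}

randomTrace <- function(pAbsent = 0.3) {
  r <- sample(1:256, 50, replace = TRUE)
  r[runif(50) < pAbsent] <- NA
  as.integer(r)
}

## random anatomically ordered annotation (ELM < EZ < RPE per column)
randomAnnotation <- function(pAbsent = 0.2) {
  rpe <- sample(150:230, 1) + sample(-2:2, 50, replace = TRUE)
  ez <- rpe - sample(8:20, 1)
  elm <- ez - sample(5:12, 1)
  drop <- function(tr) { tr[runif(50) < pAbsent] <- NA; as.integer(tr) }
  AnnotationSet(drop(elm), drop(ez), as.integer(rpe))
}

randomContingency <- function(nr = 2, nc = 2, nmax = 60) {
  repeat {
    m <- matrix(rpois(nr * nc, sample(2:8, 1)), nr, nc)
    if (sum(m) > 0 && sum(m) <= nmax && all(rowSums(m) > 0) && all(colSums(m) > 0))
      return(m)
  }
}

uniformScan <- function(value, B = 0) {
  TrimmedBScan(matrix(value, 256, 50), vitreousBrightness = B)
}
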