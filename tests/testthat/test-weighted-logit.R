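test_that("sigmoid is stable and symmetric", {
  expect_equal(sigmoid(0), 0.5)
  ## no overflow at extreme arguments; value saturates into (1 - 1e-300, 1]
  expect_true(is.finite(sigmoid(710)))
  expect_equal(sigmoid(710), 1)
  expect_gt(sigmoid(-710), 0 - 1e-300)
  expect_equal(sigmoid(-710) + sigmoid(710), 1)
  set.seed(61)
  z <- runif(100, -50, 50)
  expect_equal(sigmoid(z) + sigmoid(-z), rep(1, 100))
})

test_that("the weighted penalized loss evaluates the printed form", {
  set.seed(62)
  X <- matrix(rnorm(30 * 4), 30, 4)
  y <- rbinom(30, 1, 0.5)

  ## zero model, unweighted, no effective penalty: log 2
  expect_equal(logitLoss(rep(0, 4), 0, X, y, C = 1e12), log(2))

  ## zero design, all-ones labels, alpha = (1, 1): log 2 + penalty 2/C
  X0 <- matrix(0, 10, 2)
  expect_equal(logitLoss(c(1, 1), 0, X0, rep(1, 10), C = 1), log(2) + 2)

  ## random instances vs an independently coded term-by-term oracle
  for (i in 1:10) {
    a <- rnorm(4); b <- rnorm(1); C <- runif(1, 0.1, 10)
    w0 <- runif(1, 0.5, 3); w1 <- runif(1, 0.5, 3)
    expect_equal(logitLoss(a, b, X, y, C, w0, w1),
                 oracleLoss(a, b, X, y, C, w0, w1), tolerance = 1e-12)
  }
  expect_error(logitLoss(c(1, 1), 0, X, y, C = 1), "length")
})

test_that("the analytic gradient matches central finite differences", {
  set.seed(63)
  h <- 1e-6
  for (i in 1:50) {
    m <- sample(10:40, 1); p <- sample(2:6, 1)
    X <- matrix(rnorm(m * p), m, p)
    y <- rbinom(m, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    a <- rnorm(p); b <- rnorm(1)
    C <- runif(1, 0.1, 10); w0 <- runif(1, 0.5, 3); w1 <- runif(1, 0.5, 3)
    g <- logitGradient(a, b, X, y, C, w0, w1)
    par <- c(a, b)
    gFd <- vapply(seq_along(par), function(j) {
      e <- numeric(length(par)); e[j] <- h
      pp <- par + e; pm <- par - e
      (logitLoss(pp[1:p], pp[p + 1], X, y, C, w0, w1) -
         logitLoss(pm[1:p], pm[p + 1], X, y, C, w0, w1)) / (2 * h)
    }, 0)
    expect_lt(max(abs(g - gFd)) / max(1, max(abs(gFd))), 1e-5)
  }
})

test_that("the quasi-Newton fit reaches the convex optimum", {
  ## separable 1-D data forces a positive slope
  x <- matrix(c(-3, -2, -1, 1, 2, 3), ncol = 1)
  y <- c(0, 0, 0, 1, 1, 1)
  fit <- fitWeightedLogit(x, y, C = 1)
  expect_gt(fit@alpha[1], 0)
  expect_true(fit@converged)

  ## first-order condition at the reported optimum
  g <- logitGradient(fit@alpha, fit@intercept, x, y, 1, 1, 1)
  expect_lt(max(abs(g)), 1e-6)

  ## flipping labels negates coefficients and intercept (equal weights)
  set.seed(64)
  X <- matrix(rnorm(80 * 3), 80, 3)
  yb <- rbinom(80, 1, sigmoid(X %*% c(1, -1, 0.5)))
  f1 <- fitWeightedLogit(X, yb, C = 2)
  f2 <- fitWeightedLogit(X, 1 - yb, C = 2)
  expect_equal(f2@alpha, -f1@alpha, tolerance = 1e-6)
  expect_equal(f2@intercept, -f1@intercept, tolerance = 1e-6)
})

test_that("the fit agrees with an independent ridge-logistic solver", {
  library(glmnet)
  set.seed(65)
  n <- 150; p <- 4
  X <- matrix(rnorm(n * p), n, p)
  y <- rbinom(n, 1, sigmoid(X %*% c(0.8, -0.6, 0.4, 0) + 0.2))

  ## unweighted: glmnet objective -(1/n) loglik + (lambda/2)|alpha|^2,
  ## so lambda = 2/C matches the 1/C sum-of-squares penalty
  for (C in c(0.1, 1, 10)) {
    ours <- fitWeightedLogit(X, y, C)
    ref <- glmnet(X, y, family = "binomial", alpha = 0, lambda = 2 / C,
                  standardize = FALSE, thresh = 1e-14)
    expect_lt(max(abs(ours@alpha - as.numeric(coef(ref))[-1])), 1e-4)
    expect_lt(abs(ours@intercept - as.numeric(coef(ref))[1]), 1e-4)
  }

  ## class-weighted: glmnet rescales weights to sum to n, giving
  ## lambda = 2 n / (C * sum(w))
  w0 <- 1; w1 <- 43 / 23; C <- 0.5
  wts <- ifelse(y == 1, w0, w1)
  ours <- fitWeightedLogit(X, y, C, w0, w1)
  ref <- glmnet(X, y, family = "binomial", alpha = 0, weights = wts,
                lambda = 2 * n / (C * sum(wts)), standardize = FALSE,
                thresh = 1e-14)
  expect_lt(max(abs(ours@alpha - as.numeric(coef(ref))[-1])), 1e-4)
})

test_that("regularization and class weights act in the expected directions", {
  x <- matrix(c(-2, -1, -0.5, 0.5, 1, 2), ncol = 1)
  y <- c(0, 0, 0, 1, 1, 1)

  ## C -> 0+: coefficients collapse to zero
  expect_lt(abs(fitWeightedLogit(x, y, C = 1e-8)@alpha[1]), 1e-3)

  ## growing C on separable data: coefficient norm nondecreasing
  norms <- vapply(c(0.01, 0.1, 1, 10, 100),
                  function(C) abs(fitWeightedLogit(x, y, C)@alpha[1]), 0)
  expect_true(all(diff(norms) >= -1e-8))

  ## upweighting the minority class never lowers its recall at 0.5
  set.seed(66)
  X <- matrix(rnorm(120 * 2), 120, 2)
  yb <- rbinom(120, 1, sigmoid(X %*% c(1.2, -0.8) + 1))  # class 0 minority
  recall0 <- vapply(c(1, 2, 4, 8), function(w) {
    fit <- fitWeightedLogit(X, yb, C = 10, w0 = 1, w1 = w)
    pred <- predictProba(fit, X) < 0.5
    sum(pred & yb == 0) / sum(yb == 0)
  }, 0)
  expect_true(all(diff(recall0) >= 0))
})

test_that("the loss is convex along random segments", {
  set.seed(67)
  X <- matrix(rnorm(40 * 3), 40, 3)
  y <- rbinom(40, 1, 0.5)
  for (i in 1:200) {
    p1 <- rnorm(4); p2 <- rnorm(4); t <- runif(1)
    C <- runif(1, 0.5, 5)
    mid <- t * p1 + (1 - t) * p2
    f <- function(p) logitLoss(p[1:3], p[4], X, y, C)
    expect_lte(f(mid), t * f(p1) + (1 - t) * f(p2) + 1e-10)
  }
})

test_that("standardization is leakage-free and strict about variance", {
  train <- cbind(a = c(8, 10, 12, 10), b = c(0, 1, 2, 3))
  std <- standardizeFitApply(train, other = cbind(a = 14, b = 1))
  expect_equal(unname(std$other[1, "a"]), (14 - 10) / sd(train[, "a"]))
  expect_equal(colMeans(std$train), c(a = 0, b = 0), tolerance = 1e-12)
  expect_equal(apply(std$train, 2, sd), c(a = 1, b = 1), tolerance = 1e-12)

  bad <- cbind(a = c(1, 1, 1), b = c(1, 2, 3))
  expect_error(standardizeFitApply(bad), "a")

  ## held-out columns standardize to near but not exactly zero mean
  set.seed(68)
  tr <- matrix(rnorm(500), 250, 2); te <- matrix(rnorm(200), 100, 2)
  s <- standardizeFitApply(tr, te)
  expect_lt(max(abs(colMeans(s$other))), 0.5)
  expect_gt(max(abs(colMeans(s$other))), 1e-6)
})

test_that("predicted probabilities are sigmoid-linear in the features", {
  m <- new(Class = "LogitModel", alpha = c(0, 0), intercept = 0, C = 1,
           w0 = 1, w1 = 1, converged = TRUE, nIter = 0L,
           featureNames = c("a", "b"))
  X <- matrix(rnorm(20), 10, 2)
  expect_equal(predictProba(m, X), rep(0.5, 10))

  m@alpha <- c(2, 0)
  xs <- cbind(seq(-2, 2, length.out = 9), 0)
  expect_true(all(diff(predictProba(m, xs)) > 0))
  expect_error(predictProba(m, matrix(0, 2, 3)), "mismatch")
})
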