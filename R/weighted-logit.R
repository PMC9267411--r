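#' Numerically stable sigmoid
#'
#' `sigmoid(z) = 1 / (1 + exp(-z))`, evaluated without overflow for any
#' finite `z`; satisfies `sigmoid(z) + sigmoid(-z) = 1`.
#'
#' @param z numeric vector.
#' @return values in (0, 1).
#' @export
sigmoid <- function(z) {
  out <- numeric(length(z))
  pos <- z >= 0
  out[pos] <- 1 / (1 + exp(-z[pos]))
  e <- exp(z[!pos])
  out[!pos] <- e / (1 + e)
  out
}

## log(sigmoid(z)) without underflow
.logSigmoid <- function(z) {
  out <- numeric(length(z))
  pos <- z >= 0
  out[pos] <- -log1p(exp(-z[pos]))
  out[!pos] <- z[!pos] - log1p(exp(z[!pos]))
  out
}

.checkDesign <- function(X, y, alpha) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("X and y have inconsistent shapes")
  if (ncol(X) != length(alpha)) stop("alpha length must match ncol(X)")
  if (anyNA(X) || anyNA(y)) stop("missing values in the design")
  if (!all(y %in% c(0, 1))) stop("labels must be coded 0/1")
  X
}

#' Class-weighted L2-penalized logistic loss
#'
#' The loss minimized by [fitWeightedLogit()]:
#' \deqn{E(\alpha) = -\frac{1}{m}\sum_i\left[w_0\, y_i \log\sigma_i +
#'   w_1\,(1-y_i)\log(1-\sigma_i)\right] + \frac{1}{C}\sum_j \alpha_j^2}
#' with \eqn{\sigma_i = \sigma(\alpha^\top x_i + b)}.  `w0` weights the
#' y = 1 terms and `w1` the y = 0 terms; the intercept `b` is excluded
#' from the penalty.  Note the penalty is `1/C` times the plain sum of
#' squares (no 1/2 factor); equivalences to other conventions (e.g. a
#' ridge-logistic `lambda` of `2m/(C * sum of weights)`) follow from
#' rescaling.
#'
#' @param alpha coefficient vector.
#' @param intercept unpenalized bias.
#' @param X design matrix (samples x features), normally standardized.
#' @param y 0/1 labels (1 = poor prognosis, Group B).
#' @param C regularization parameter > 0.
#' @param w0,w1 class weights for the y = 1 and y = 0 terms.
#' @return The scalar loss.
#' @export
logitLoss <- function(alpha, intercept, X, y, C, w0 = 1, w1 = 1) {
  X <- .checkDesign(X, y, alpha)
  stopifnot(C > 0, w0 > 0, w1 > 0)
  eta <- drop(X %*% alpha) + intercept
  ll <- w0 * y * .logSigmoid(eta) + w1 * (1 - y) * .logSigmoid(-eta)
  -mean(ll) + sum(alpha^2) / C
}

#' Analytic gradient of the weighted logistic loss
#'
#' Gradient of [logitLoss()] with respect to `(alpha, intercept)`; the
#' penalty contributes `2 * alpha / C` per coefficient and nothing for the
#' intercept.
#'
#' @inheritParams logitLoss
#' @return numeric vector of length `ncol(X) + 1`; the last entry is the
#'   intercept derivative.
#' @export
logitGradient <- function(alpha, intercept, X, y, C, w0 = 1, w1 = 1) {
  X <- .checkDesign(X, y, alpha)
  stopifnot(C > 0, w0 > 0, w1 > 0)
  m <- nrow(X)
  eta <- drop(X %*% alpha) + intercept
  p <- sigmoid(eta)
  ## d/d eta of the unpenalized per-sample log-likelihood term
  dEta <- -(w0 * y * (1 - p) - w1 * (1 - y) * p) / m
  c(drop(crossprod(X, dEta)) + 2 * alpha / C, sum(dEta))
}

#' Fit the class-weighted penalized logistic model
#'
#' Minimizes [logitLoss()] by L-BFGS-B from a zero start (the problem is
#' convex, so no restarts are needed).  Convergence is declared when the
#' projected gradient falls below 1e-8 or the relative loss change falls
#' below 1e-10 within `maxit` iterations; non-convergence is flagged and
#' warned about but the best iterate is still returned.
#'
#' @inheritParams logitLoss
#' @param maxit iteration cap (default 1000).
#' @return A [LogitModel-class].
#' @export
fitWeightedLogit <- function(X, y, C, w0 = 1, w1 = 1, maxit = 1000L) {
  X <- as.matrix(X)
  nms <- colnames(X)
  if (is.null(nms)) nms <- paste0("x", seq_len(ncol(X)))
  p <- ncol(X)
  fn <- function(par) logitLoss(par[seq_len(p)], par[p + 1L], X, y, C, w0, w1)
  gr <- function(par) logitGradient(par[seq_len(p)], par[p + 1L], X, y, C, w0, w1)
  res <- stats::optim(rep(0, p + 1L), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit, pgtol = 1e-8,
                                     factr = 1e-10 / .Machine$double.eps))
  conv <- res$convergence == 0L
  if (!conv) warning("quasi-Newton fit did not converge: ", res$message)
  new(Class = "LogitModel", alpha = res$par[seq_len(p)], intercept = res$par[p + 1L],
      C = as.numeric(C), w0 = as.numeric(w0), w1 = as.numeric(w1),
      converged = conv, nIter = as.integer(res$counts[["function"]]),
      featureNames = nms)
}

#' Standardize features on training statistics only
#'
#' Computes per-column z-scores (mean 0, SD 1) from the training matrix
#' and applies the same transformation to an optional second matrix, so no
#' information leaks from held-out data into the scaling.  Categorical
#' 0/1/2 grades are treated as numeric columns like everything else.
#'
#' @param train numeric training matrix (samples x features).
#' @param other optional matrix to transform with the training statistics.
#' @return list with `train`, `other` (or `NULL`), `center`, `scale`.
#' @export
standardizeFitApply <- function(train, other = NULL) {
  train <- as.matrix(train)
  if (nrow(train) < 2L) stop("need at least two training rows")
  center <- colMeans(train)
  scale <- apply(train, 2, stats::sd)
  zero <- scale <= 0 | !is.finite(scale)
  if (any(zero))
    stop("zero-variance training column(s): ",
         paste(colnames(train)[zero], collapse = ", "))
  list(train = sweep(sweep(train, 2, center), 2, scale, "/"),
       other = if (!is.null(other))
         sweep(sweep(as.matrix(other), 2, center), 2, scale, "/"),
       center = center, scale = scale)
}

#' Predicted probability of poor prognosis
#'
#' `sigmoid(alpha' x + intercept)` per row of `X`, which must be on the
#' same standardized scale the model was fitted on.
#'
#' @param model a [LogitModel-class].
#' @param X standardized feature matrix.
#' @return probabilities in (0, 1), one per row.
#' @export
predictProba <- function(model, X) {
  stopifnot(is(model, "LogitModel"))
  X <- as.matrix(X)
  if (ncol(X) != length(model@alpha)) stop("feature count mismatch")
  sigmoid(drop(X %*% model@alpha) + model@intercept)
}
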