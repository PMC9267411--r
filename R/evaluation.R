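#' Configuration of the two-stage evaluation experiment
#'
#' @param nRepeats number of repeated stratified splits per stage
#'   (default 100).
#' @param testFraction held-out fraction per class (default 0.2).
#' @param kFolds folds of the stage-1 cross-validated grid search
#'   (default 4).
#' @param cGrid candidate regularization parameters (default
#'   0.001, 0.01, 0.1, 1, 10, 100).
#' @param seed master seed; all stage randomness derives from it.
#' @return A validated list of class `experimentConfig`.
#' @export
experimentConfig <- function(nRepeats = 100L, testFraction = 0.2,
                             kFolds = 4L, cGrid = c(0.001, 0.01, 0.1, 1, 10, 100),
                             seed = 1L) {
  stopifnot(nRepeats >= 1L, testFraction > 0, testFraction < 1,
            kFolds >= 2L, length(cGrid) >= 1L, all(cGrid > 0))
  structure(list(nRepeats = as.integer(nRepeats), testFraction = testFraction,
                 kFolds = as.integer(kFolds), cGrid = sort(unique(cGrid)),
                 seed = as.integer(seed)),
            class = "experimentConfig")
}

#' Stratified train/test split
#'
#' Samples, independently and uniformly within each class, a test set of
#' `round(testFraction * class size)` members (half-up rounding, so 23
#' gives 5 and 43 gives 9 at 20%); the remaining indices form the training
#' set.  Class proportions are thereby preserved as closely as rounding
#' allows.
#'
#' @param labels class labels (any two or more levels).
#' @param testFraction fraction held out per class.
#' @return list with integer index vectors `train` and `test`.
#' @export
stratifiedSplit <- function(labels, testFraction = 0.2) {
  stopifnot(testFraction > 0, testFraction < 1)
  test <- integer(0)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < 2L) stop("each class needs at least 2 members")
    nTest <- roundHalfUp(testFraction * length(idx))
    nTest <- min(max(nTest, 1L), length(idx) - 1L)
    test <- c(test, sample(idx, nTest))
  }
  test <- sort(test)
  list(train = setdiff(seq_along(labels), test), test = test)
}

#' Stratified k-fold partition
#'
#' Shuffles each class and deals its members round-robin over the k folds,
#' so per-fold class counts differ by at most one within every class and
#' the folds partition the data.
#'
#' @param labels class labels.
#' @param k number of folds.
#' @return integer vector of fold ids (1..k), parallel to `labels`.
#' @export
stratifiedKfold <- function(labels, k) {
  stopifnot(k >= 2L)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k) stop("class smaller than k")
    fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Rank-based ROC AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney statistic: the
#' probability that a random positive scores above a random negative, with
#' ties credited 1/2.  Equals the trapezoidal area under the empirical ROC
#' curve.
#'
#' @param scores numeric scores (larger = more positive).
#' @param labels 0/1 or logical labels; 1/`TRUE` is the positive class.
#' @return AUC in [0, 1].
#' @export
rocAuc <- function(scores, labels) {
  y <- as.logical(labels)
  if (length(scores) != length(y)) stop("scores and labels differ in length")
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated grid search for the regularization parameter
#'
#' For each candidate C, runs a stratified k-fold cross-validation on the
#' training data (one fold partition shared across the grid):
#' standardization and fitting happen inside each fold on its training
#' part, and the fold AUC is measured on the held-out part.  Returns the C
#' with the highest mean AUC; ties break toward the smaller C (stronger
#' regularization).
#'
#' @param X numeric feature matrix (unstandardized).
#' @param y 0/1 labels (1 = Group B).
#' @param config an [experimentConfig()].
#' @param w0,w1 class weights passed to [fitWeightedLogit()].
#' @return list with `bestC` and `meanAuc` (named by grid value).
#' @export
gridSearchC <- function(X, y, config = experimentConfig(), w0 = 1, w1 = 1) {
  X <- as.matrix(X)
  fold <- stratifiedKfold(y, config$kFolds)
  meanAuc <- vapply(config$cGrid, function(C) {
    aucs <- vapply(seq_len(config$kFolds), function(f) {
      tr <- fold != f
      std <- standardizeFitApply(X[tr, , drop = FALSE], X[!tr, , drop = FALSE])
      fit <- fitWeightedLogit(std$train, y[tr], C, w0, w1)
      rocAuc(predictProba(fit, std$other), y[!tr])
    }, 0)
    mean(aucs)
  }, 0)
  names(meanAuc) <- as.character(config$cGrid)
  best <- config$cGrid[which.max(meanAuc)]   # grid sorted ascending: first max
  list(bestC = best, meanAuc = meanAuc)
}

#' Stage 1: repeated selection of the regularization parameter
#'
#' Repeats `nRepeats` times: draw a stratified train/test split, then
#' grid-search C by stratified k-fold cross-validated AUC on the training
#' part.  Returns how often each grid value was selected and the modal
#' value (ties toward smaller C), which is the C fixed for stage 2.
#'
#' @inheritParams gridSearchC
#' @return list with `frequency` (named counts over the grid, summing to
#'   `nRepeats`) and `modalC`.
#' @export
stage1 <- function(X, y, config = experimentConfig(), w0 = 1, w1 = 1) {
  set.seed(substreamSeed(config$seed, 1L))
  picks <- numeric(config$nRepeats)
  for (r in seq_len(config$nRepeats)) {
    sp <- stratifiedSplit(y, config$testFraction)
    picks[r] <- gridSearchC(as.matrix(X)[sp$train, , drop = FALSE],
                            y[sp$train], config, w0, w1)$bestC
  }
  freq <- stats::setNames(
    vapply(config$cGrid, function(C) sum(picks == C), 0L),
    as.character(config$cGrid))
  list(frequency = freq, modalC = config$cGrid[which.max(freq)])
}

#' Stage 2: repeated evaluation at a fixed regularization parameter
#'
#' Repeats `nRepeats` times: draw a stratified train/test split,
#' standardize on the training part, fit the class-weighted penalized
#' logistic model at the fixed C, and record the held-out AUC and the
#' fitted coefficients.  Class weights default to the inverse group-size
#' ratio (the minority good-prognosis class weighted `nB/nA` times more);
#' pass `w0`/`w1` to override.
#'
#' @param X numeric feature matrix with named columns (unstandardized).
#' @param y 0/1 labels (1 = Group B).
#' @param C the fixed regularization parameter.
#' @param config an [experimentConfig()].
#' @param w0 weight of the y = 1 (Group B) loss terms; default 1.
#' @param w1 weight of the y = 0 (Group A) loss terms; default the
#'   imbalance ratio `sum(y == 1) / sum(y == 0)`.
#' @return An [ExperimentResult-class].
#' @export
stage2 <- function(X, y, C, config = experimentConfig(),
                   w0 = 1, w1 = sum(y == 1) / sum(y == 0)) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  set.seed(substreamSeed(config$seed, 2L))
  aucs <- numeric(config$nRepeats)
  coefs <- matrix(NA_real_, config$nRepeats, ncol(X),
                  dimnames = list(NULL, colnames(X)))
  intercepts <- numeric(config$nRepeats)
  for (r in seq_len(config$nRepeats)) {
    sp <- stratifiedSplit(y, config$testFraction)
    std <- standardizeFitApply(X[sp$train, , drop = FALSE],
                               X[sp$test, , drop = FALSE])
    fit <- fitWeightedLogit(std$train, y[sp$train], C, w0, w1)
    aucs[r] <- rocAuc(predictProba(fit, std$other), y[sp$test])
    coefs[r, ] <- fit@alpha
    intercepts[r] <- fit@intercept
  }
  new(Class = "ExperimentResult", aucValues = aucs, coefficients = coefs,
      intercepts = intercepts, C = as.numeric(C),
      seed = as.integer(config$seed))
}
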