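#' @import methods
#' @importFrom stats rnorm runif rbinom optim sd ks.test pnorm quantile
#' @importFrom utils read.csv write.csv
NULL

SCAN_ROWS <- 256L
SCAN_COLS <- 50L

#' Trimmed OCT B-scan
#'
#' An 8-bit-range grayscale grid of 256 axial rows by 50 lateral columns,
#' trimmed around the fovea, together with the mean brightness of the
#' liquefied-vitreous region.  Row 1 is the innermost (vitreous) side; rows
#' increase toward the retinal pigment epithelium.  Pixel values live in
#' [0, 255]; they are stored as numeric so that brightness-standardized
#' scans (which are no longer integral) use the same class.
#'
#' @slot pixels numeric matrix, 256 rows x 50 columns, values in [0, 255].
#' @slot vitreousBrightness mean brightness of the liquefied vitreous,
#'   in [0, 255); the reference used by [standardizeBrightness()].
#' @export
setClass("TrimmedBScan",
  representation(pixels = "matrix", vitreousBrightness = "numeric"))

setValidity("TrimmedBScan", function(object) {
  p <- object@pixels
  if (!is.numeric(p) || !identical(dim(p), c(SCAN_ROWS, SCAN_COLS)))
    return(sprintf("pixels must be a numeric %d x %d matrix", SCAN_ROWS, SCAN_COLS))
  if (anyNA(p) || min(p) < 0 || max(p) > 255)
    return("pixel values must be finite and in [0, 255]")
  b <- object@vitreousBrightness
  if (length(b) != 1L || !is.finite(b) || b < 0 || b >= 255)
    return("vitreousBrightness must be a single value in [0, 255)")
  TRUE
})

#' Construct a trimmed B-scan
#'
#' @param pixels numeric matrix, 256 rows (axial) x 50 columns (lateral),
#'   values in [0, 255].
#' @param vitreousBrightness mean brightness of the liquefied-vitreous
#'   region.  If `NULL`, it is estimated with
#'   [estimateVitreousBrightness()] from the innermost rows of the scan.
#' @return A [TrimmedBScan-class] object.
#' @export
TrimmedBScan <- function(pixels, vitreousBrightness = NULL) {
  storage.mode(pixels) <- "double"
  if (is.null(vitreousBrightness))
    vitreousBrightness <- estimateVitreousBrightness(pixels)
  new("TrimmedBScan", pixels = pixels,
      vitreousBrightness = as.numeric(vitreousBrightness))
}

#' Estimate vitreous reference brightness
#'
#' The liquefied vitreous occupies the innermost (top) part of a trimmed
#' scan; its mean brightness is the reference `B` of the brightness
#' standardization.
#'
#' @param pixels numeric matrix of pixel brightness.
#' @param rows row indices taken as vitreous; default the innermost 40.
#' @return Mean brightness over the given rows, capped just below 255.
#' @export
estimateVitreousBrightness <- function(pixels, rows = 1:40) {
  min(mean(pixels[rows, , drop = FALSE]), 255 - 1e-6)
}

#' @describeIn TrimmedBScan pixel grid accessor
#' @param object,x a `TrimmedBScan`
#' @export
pixels <- function(x) x@pixels

#' @describeIn TrimmedBScan vitreous reference brightness accessor
#' @export
vitreousBrightness <- function(x) x@vitreousBrightness

setMethod("show", "TrimmedBScan", function(object) {
  cat(sprintf("TrimmedBScan: %d x %d, brightness range [%.1f, %.1f], vitreous B = %.2f\n",
              nrow(object@pixels), ncol(object@pixels),
              min(object@pixels), max(object@pixels),
              object@vitreousBrightness))
})

#' Per-column layer annotations of a trimmed B-scan
#'
#' Row positions of the external limiting membrane (ELM), ellipsoid zone
#' (EZ), and retinal pigment epithelium (RPE) at each of the 50 columns.
#' Each trace is a length-50 integer vector of 1-based row indices; `NA`
#' marks a column where the layer is absent (vanished).  Wherever all three
#' layers are present the anatomical order ELM < EZ < RPE (inner to outer)
#' must hold.
#'
#' @slot elm,ez,rpe integer vectors of length 50; `NA` = layer absent.
#' @export
setClass("AnnotationSet",
  representation(elm = "integer", ez = "integer", rpe = "integer"))

setValidity("AnnotationSet", function(object) {
  for (nm in c("elm", "ez", "rpe")) {
    tr <- slot(object, nm)
    if (length(tr) != SCAN_COLS)
      return(sprintf("%s trace must have length %d", nm, SCAN_COLS))
    ok <- is.na(tr) | (tr >= 1L & tr <= SCAN_ROWS)
    if (!all(ok))
      return(sprintf("%s trace rows must be in [1, %d] or NA", nm, SCAN_ROWS))
  }
  all3 <- !is.na(object@elm) & !is.na(object@ez) & !is.na(object@rpe)
  if (any(all3 & !(object@elm < object@ez & object@ez < object@rpe)))
    return("layer order violated: need ELM < EZ < RPE where all present")
  TRUE
})

#' Construct an annotation set
#'
#' @param elm,ez,rpe numeric vectors of length 50 with 1-based row indices
#'   (`NA` where the layer is absent).
#' @return An [AnnotationSet-class] object.
#' @export
AnnotationSet <- function(elm, ez, rpe) {
  new("AnnotationSet", elm = as.integer(round(elm)),
      ez = as.integer(round(ez)), rpe = as.integer(round(rpe)))
}

#' Extract one layer trace from an annotation set
#'
#' @param ann an [AnnotationSet-class].
#' @param layer one of `"elm"`, `"ez"`, `"rpe"`.
#' @return Integer vector of length 50 (`NA` = absent).
#' @export
layerTrace <- function(ann, layer = c("elm", "ez", "rpe")) {
  slot(ann, match.arg(layer))
}

setMethod("show", "AnnotationSet", function(object) {
  pres <- function(tr) sum(!is.na(tr))
  cat(sprintf("AnnotationSet: ELM %d/50, EZ %d/50, RPE %d/50 columns present\n",
              pres(object@elm), pres(object@ez), pres(object@rpe)))
})

#' Class-weighted L2-regularized logistic model
#'
#' Fitted coefficients of the penalized logistic loss (see [logitLoss()]);
#' labels are coded y = 1 for the poor-prognosis group (Group B) and
#' y = 0 for the good-prognosis group (Group A).  The intercept is
#' unpenalized.
#'
#' @slot alpha coefficient vector on the standardized feature scale.
#' @slot intercept unpenalized bias term.
#' @slot C regularization parameter (> 0); the penalty is
#'   `sum(alpha^2) / C`.
#' @slot w0,w1 class weights attached to the y = 1 and y = 0 loss terms.
#' @slot converged logical convergence flag.
#' @slot nIter number of quasi-Newton iterations used.
#' @slot featureNames names of the design-matrix columns.
#' @export
setClass("LogitModel",
  representation(alpha = "numeric", intercept = "numeric", C = "numeric",
                 w0 = "numeric", w1 = "numeric", converged = "logical",
                 nIter = "integer", featureNames = "character"))

setValidity("LogitModel", function(object) {
  if (!all(is.finite(object@alpha)) || !is.finite(object@intercept))
    return("coefficients must be finite")
  if (object@C <= 0) return("C must be > 0")
  if (object@w0 <= 0 || object@w1 <= 0) return("class weights must be > 0")
  TRUE
})

setMethod("show", "LogitModel", function(object) {
  cat(sprintf("LogitModel: %d features, C = %g, weights (w0, w1) = (%.3f, %.3f)\n",
              length(object@alpha), object@C, object@w0, object@w1))
  cat(sprintf("  converged: %s in %d iterations\n",
              object@converged, object@nIter))
  cf <- c(object@alpha, `(intercept)` = object@intercept)
  names(cf)[seq_along(object@alpha)] <- object@featureNames
  print(round(cf, 4))
})

#' @describeIn LogitModel named coefficient vector (without intercept)
#' @param object a `LogitModel`
#' @export
modelCoefficients <- function(object) {
  stats::setNames(object@alpha, object@featureNames)
}

#' Candidate-variable screening result
#'
#' Output of [selectCandidates()]: one row per candidate variable with the
#' test applied, its p-value and selection flag, plus the variables retained
#' after the multicollinearity elimination loop and their final R-squared
#' values against the other retained variables.
#'
#' @slot screen data.frame with columns `variable`, `type`, `test`, `p`,
#'   `selected`.
#' @slot retained character vector of retained explanatory variables.
#' @slot r2 named numeric of final R-squared values for the retained set.
#' @slot alpha significance level used.
#' @slot r2Threshold elimination threshold on R-squared.
#' @export
setClass("CandidateScreen",
  representation(screen = "data.frame", retained = "character",
                 r2 = "numeric", alpha = "numeric", r2Threshold = "numeric"))

setMethod("show", "CandidateScreen", function(object) {
  cat(sprintf("CandidateScreen: %d candidates, %d selected (p < %g), %d retained after R2 > %g elimination\n",
              nrow(object@screen), sum(object@screen$selected),
              object@alpha, length(object@retained), object@r2Threshold))
  print(object@screen, digits = 4)
})

#' @describeIn CandidateScreen per-variable screening table
#' @param object a `CandidateScreen`
#' @export
screenTable <- function(object) object@screen

#' @describeIn CandidateScreen retained explanatory variables
#' @export
retainedVariables <- function(object) object@retained

#' Two-stage evaluation result
#'
#' AUC values and fitted coefficients over the repeated stratified
#' train/test splits of the second experiment stage.
#'
#' @slot aucValues test-set AUC of each repeat.
#' @slot coefficients matrix (repeats x features) of fitted coefficients on
#'   the standardized scale.
#' @slot intercepts fitted intercepts per repeat.
#' @slot C the fixed regularization parameter used.
#' @slot seed master seed of the stage.
#' @export
setClass("ExperimentResult",
  representation(aucValues = "numeric", coefficients = "matrix",
                 intercepts = "numeric", C = "numeric", seed = "integer"))

setValidity("ExperimentResult", function(object) {
  if (any(object@aucValues < 0 | object@aucValues > 1))
    return("AUC values must lie in [0, 1]")
  if (nrow(object@coefficients) != length(object@aucValues))
    return("one coefficient row per repeat required")
  TRUE
})

setMethod("show", "ExperimentResult", function(object) {
  s <- aucSummary(object)
  cat(sprintf("ExperimentResult: %d repeats at C = %g\n",
              length(object@aucValues), object@C))
  cat(sprintf("  AUC mean %.3f, SD %.3f\n", s[["mean"]], s[["sd"]]))
  print(coefficientTable(object), digits = 3)
})

#' @describeIn ExperimentResult AUC mean and standard deviation
#' @param object an `ExperimentResult`
#' @export
aucSummary <- function(object) {
  c(mean = mean(object@aucValues), sd = stats::sd(object@aucValues))
}

#' @describeIn ExperimentResult per-coefficient mean, SD and 95% CI of the
#'   mean (normal approximation over the repeats)
#' @export
coefficientTable <- function(object) {
  m <- colMeans(object@coefficients)
  s <- apply(object@coefficients, 2, stats::sd)
  half <- 1.96 * s / sqrt(nrow(object@coefficients))
  data.frame(variable = colnames(object@coefficients),
             mean = m, sd = s, lower = m - half, upper = m + half,
             row.names = NULL)
}
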