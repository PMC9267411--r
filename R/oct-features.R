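#' Standardize scan brightness against the vitreous reference
#'
#' OCT brightness varies between acquisitions; the scan is rescaled so that
#' layer brightness becomes comparable across eyes.  With `B` the mean
#' brightness of the liquefied vitreous, every pixel is multiplied by the
#' gain `255 / (255 - B)` and capped at 255.  A scan with `B = 0` is
#' returned unchanged.
#'
#' @param img a [TrimmedBScan-class].
#' @return A [TrimmedBScan-class] with rescaled pixels; its
#'   `vitreousBrightness` is the same gain applied to the input reference
#'   (kept strictly below 255).
#' @export
standardizeBrightness <- function(img) {
  stopifnot(is(img, "TrimmedBScan"))
  B <- img@vitreousBrightness
  if (!is.finite(B) || B >= 255)
    stop("invalid reference brightness: vitreous B must be < 255")
  gain <- 255 / (255 - B)
  px <- pmin(img@pixels * gain, 255)
  new("TrimmedBScan", pixels = px,
      vitreousBrightness = min(B * gain, 255 - 1e-6))
}

## brightness at the annotated pixel of each column; absent columns -> NA
.traceBrightness <- function(img, trace) {
  px <- img@pixels
  out <- rep(NA_real_, SCAN_COLS)
  j <- which(!is.na(trace))
  out[j] <- px[cbind(trace[j], j)]
  out
}

.checkTrace <- function(trace) {
  if (length(trace) != SCAN_COLS)
    stop(sprintf("trace must have length %d", SCAN_COLS))
  bad <- !is.na(trace) & (trace < 1 | trace > SCAN_ROWS)
  if (any(bad)) stop("trace rows out of grid bounds")
  invisible(trace)
}

#' Layer continuity-org: summed brightness under a layer trace
#'
#' The sum over the 50 columns of the (standardized) brightness at the
#' annotated layer pixel.  Columns where the layer is absent contribute a
#' brightness of 1, so an entirely vanished layer scores 50.
#'
#' @param img a [TrimmedBScan-class], normally already brightness-standardized.
#' @param trace integer vector of length 50 of 1-based row indices
#'   (`NA` = absent), e.g. from [layerTrace()].
#' @return The continuity-org sum (a single number).
#' @export
continuityOrg <- function(img, trace) {
  stopifnot(is(img, "TrimmedBScan"))
  .checkTrace(trace)
  b <- .traceBrightness(img, trace)
  sum(ifelse(is.na(b), 1, b))
}

#' Layer clarity: brightness contrast of a layer against its surround
#'
#' Per column with an annotated row r, the ratio of the brightness at r to
#' the mean brightness of the 6 pixels at rows r-3..r-1 and r+1..r+3 (the
#' window is clamped at the grid edges; the neighborhood mean is floored at
#' 1 to guard the division).  Columns without a line contribute a ratio of
#' 1.  The mean of the 50 per-column ratios is returned, so a perfectly
#' uniform scan has clarity exactly 1 and typical clinical values sit near
#' 1.1-1.2.
#'
#' @inheritParams continuityOrg
#' @return Mean per-column brightness ratio.
#' @export
layerClarity <- function(img, trace) {
  stopifnot(is(img, "TrimmedBScan"))
  .checkTrace(trace)
  px <- img@pixels
  ratios <- rep(1, SCAN_COLS)
  for (j in which(!is.na(trace))) {
    r <- trace[j]
    nbr <- setdiff(max(1L, r - 3L):min(SCAN_ROWS, r + 3L), r)
    denom <- max(1, mean(px[nbr, j]))
    ratios[j] <- px[r, j] / denom
  }
  mean(ratios)
}

#' Photoreceptor outer-segment area between the EZ and RPE traces
#'
#' Counts, per column where both the EZ and RPE are annotated, the pixels
#' strictly between the two rows (`rpe - ez - 1`, floored at 0); columns
#' with either trace absent contribute 0.  Adjacent traces (row difference
#' 1) therefore enclose no area.
#'
#' @param ann an [AnnotationSet-class].
#' @return Total enclosed pixel count.
#' @export
areaOuterSegments <- function(ann) {
  stopifnot(is(ann, "AnnotationSet"))
  both <- !is.na(ann@ez) & !is.na(ann@rpe)
  sum(pmax(0, ann@rpe[both] - ann@ez[both] - 1L))
}

#' Three-level continuity grade of a layer trace
#'
#' Objective surrogate for the clinical grading of layer integrity into
#' vanishing / discontinuous / continuous: with f the fraction of the 50
#' columns where the layer is present, the grade is 0 when f = 0, 2 when
#' f = 1, and 1 otherwise.
#'
#' @param trace integer vector of length 50 (`NA` = absent).
#' @return Integer grade in {0, 1, 2}.
#' @export
gradeContinuity <- function(trace) {
  .checkTrace(trace)
  f <- mean(!is.na(trace))
  if (f == 0) 0L else if (f == 1) 2L else 1L
}

#' Extract the seven handcrafted OCT features of a trimmed B-scan
#'
#' Standardizes the scan brightness once, then computes the five continuous
#' features (ELM/EZ continuity-org, ELM/EZ clarity, outer-segment area) and
#' the two categorical continuity grades.  Deterministic: identical inputs
#' give identical outputs.
#'
#' @param img a [TrimmedBScan-class] (raw, not yet standardized).
#' @param ann an [AnnotationSet-class].
#' @return A one-row data.frame with columns `elm_continuity_org`,
#'   `ez_continuity_org`, `elm_clarity`, `ez_clarity`, `area`,
#'   `elm_continuity_cat`, `ez_continuity_cat`.
#' @export
extractFeatures <- function(img, ann) {
  stopifnot(is(img, "TrimmedBScan"), is(ann, "AnnotationSet"))
  s <- standardizeBrightness(img)
  data.frame(
    elm_continuity_org = continuityOrg(s, ann@elm),
    ez_continuity_org  = continuityOrg(s, ann@ez),
    elm_clarity        = layerClarity(s, ann@elm),
    ez_clarity         = layerClarity(s, ann@ez),
    area               = areaOuterSegments(ann),
    elm_continuity_cat = gradeContinuity(ann@elm),
    ez_continuity_cat  = gradeContinuity(ann@ez))
}
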