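#' Specification of a synthetic BRVO cohort
#'
#' Holds the group sizes and all group-conditional distribution parameters
#' used by [generateCohort()]: clinical covariate means/SDs and categorical
#' proportions, and the B-scan renderer's band brightness, blur, geometry
#' and disruption parameters.  The defaults emulate a 66-eye cohort with 23
#' good-prognosis (Group A) and 43 poor-prognosis (Group B) eyes; variables
#' without a real group difference share pooled parameters across groups.
#'
#' @slot nA,nB group sizes.
#' @slot seed default random seed for [generateCohort()].
#' @slot clinical named list of clinical covariate parameters.
#' @slot image named list of renderer parameters.
#' @export
setClass("CohortSpec",
  representation(nA = "integer", nB = "integer", seed = "integer",
                 clinical = "list", image = "list"))

setValidity("CohortSpec", function(object) {
  if (object@nA < 1L || object@nB < 1L) return("group sizes must be positive")
  cl <- object@clinical
  for (p in c("pMale", "pMajor", "pRight", "pSuperior"))
    if (any(cl[[p]] < 0 | cl[[p]] > 1))
      return(sprintf("%s must be a probability", p))
  for (v in c("age", "onset_to_treatment", "bcva_baseline",
              "bcva_resolution", "resolution_weeks", "n_injections"))
    if (any(vapply(cl[[v]][c("A", "B")], function(g) g[["sd"]], 0) <= 0))
      return(sprintf("%s SDs must be positive", v))
  gp <- object@image$gradeProbs
  for (layer in c("elm", "ez")) for (g in c("A", "B")) {
    pr <- gp[[layer]][[g]]
    if (length(pr) != 3L || any(pr < 0) || abs(sum(pr) - 1) > 1e-8)
      return("grade probabilities must be length-3 simplex vectors")
  }
  TRUE
})

.groupParam <- function(mean, sd, lo, hi, dist = "normal")
  list(mean = mean, sd = sd, lo = lo, hi = hi, dist = dist)

#' Construct a cohort specification
#'
#' All defaults are calibrated so that the synthetic cohort reproduces the
#' group-conditional means, SDs and categorical proportions of the clinical
#' study the pipeline emulates: significant variables (age, baseline and
#' resolution BCVA, the five image features driven by EZ damage, and the
#' two continuity grades) are group-conditional, while variables without a
#' real group difference (sex, occlusion type, affected eye, semifield,
#' onset-to-treatment, time-to-resolution, ELM continuity-org) are drawn
#' from pooled distributions so they stay null at any sample size.
#'
#' @param nA,nB group sizes (defaults 23 and 43).
#' @param seed default seed for cohort generation.
#' @param clinical,image optional lists overriding individual entries of
#'   the default parameter lists (partial overrides are merged).
#' @return A [CohortSpec-class] object.
#' @export
cohortSpec <- function(nA = 23L, nB = 43L, seed = 1L,
                       clinical = list(), image = list()) {
  clin <- list(
    ## group-conditional clinical covariates (truncated normals)
    age = list(A = .groupParam(63.6, 12.1, 30, 95),
               B = .groupParam(69.2, 6.9, 30, 95)),
    bcva_baseline = list(A = .groupParam(0.15, 0.15, -0.3, 2),
                         B = .groupParam(0.54, 0.28, -0.3, 2)),
    ## Group A BCVA at resolution is capped at 0.15 logMAR: the good-
    ## prognosis rule requires the series, which starts there, never to
    ## exceed 0.15; Group B is floored at -0.1 so that a poor course
    ## remains reachable by bounded monthly steps.
    bcva_resolution = list(A = .groupParam(0.04, 0.09, -0.3, 0.15),
                           B = .groupParam(0.32, 0.24, -0.1, 2)),
    ## pooled (no real group difference)
    ## onset delay is right-skewed (SD > mean): lognormal with matched
    ## arithmetic mean/SD keeps the target mean without truncation bias
    onset_to_treatment = list(A = .groupParam(6.86, 7.05, 0, 45, "lognormal"),
                              B = .groupParam(6.86, 7.05, 0, 45, "lognormal")),
    resolution_weeks = list(A = .groupParam(4.5, 1.6, 1, 8),
                            B = .groupParam(4.5, 1.6, 1, 8)),
    n_injections = list(A = .groupParam(3.2, 1.9, 1, 10),
                        B = .groupParam(3.2, 1.9, 1, 10)),
    pMale = c(A = 36 / 66, B = 36 / 66),
    pMajor = c(A = 44 / 66, B = 44 / 66),
    pRight = c(A = 35 / 66, B = 35 / 66),
    pSuperior = c(A = 48 / 66, B = 48 / 66),
    ## BCVA random-walk mechanism (logMAR / month)
    bcvaStep = c(A = 0.04, B = 0.08),
    bcvaDrift = c(A = -0.010, B = -0.015),
    bcvaBounds = c(-0.30, 1.50),
    maxTries = 500L)
  img <- list(
    background = c(mean = 30, sd = 5),
    noiseSd = 8,
    rpeCenter = c(mean = 170, sd = 5),
    curvature = c(mean = 3, sd = 1.5),
    elmToEz = c(mean = 10, sd = 1, lo = 7, hi = 14),
    ezToRpe = list(A = c(mean = 15.7, sd = 2.6, lo = 6, hi = 30),
                   B = c(mean = 18.0, sd = 3.5, lo = 6, hi = 30)),
    ## band peak brightness above background and Gaussian depth blur,
    ## per group; calibrated against the extracted-feature group means
    elm = list(peak = c(A = 57, B = 80), peakSd = c(A = 18, B = 18),
               sigma = c(A = 2.45, B = 3.2), sigmaSd = c(A = 0.3, B = 0.3)),
    ez = list(peak = c(A = 122, B = 130), peakSd = c(A = 22, B = 22),
              sigma = c(A = 2.85, B = 3.45), sigmaSd = c(A = 0.3, B = 0.3)),
    rpe = list(peak = c(A = 130, B = 130), peakSd = c(A = 12, B = 12),
               sigma = c(A = 4, B = 4), sigmaSd = c(A = 0.3, B = 0.3)),
    ## P(grade 0 / 1 / 2) per layer and group
    gradeProbs = list(elm = list(A = c(0, 1, 22) / 23, B = c(6, 11, 26) / 43),
                      ez = list(A = c(0, 5, 18) / 23, B = c(8, 21, 14) / 43)),
    ## present-column fraction drawn uniformly for grade-1 layers
    grade1PresentRange = c(0.5, 0.95))
  clin[names(clinical)] <- clinical
  img[names(image)] <- image
  new("CohortSpec", nA = as.integer(nA), nB = as.integer(nB),
      seed = as.integer(seed), clinical = clin, image = img)
}

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf("CohortSpec: %d Group A + %d Group B eyes, seed %d\n",
              object@nA, object@nB, object@seed))
})

#' Synthetic cohort container
#'
#' One generated cohort: the per-patient clinical table (including the
#' monthly BCVA series in columns `bcva_m1`..`bcva_m12`, `NA` before the
#' resolution month), the rendered B-scans and their exact layer
#' annotations, and the spec/seed that produced them.
#'
#' @slot patients data.frame, one row per patient.
#' @slot scans list of [TrimmedBScan-class], parallel to `patients`.
#' @slot annotations list of [AnnotationSet-class], parallel to `patients`.
#' @slot spec the generating [CohortSpec-class].
#' @slot seed the seed actually used.
#' @export
setClass("OctCohort",
  representation(patients = "data.frame", scans = "list",
                 annotations = "list", spec = "CohortSpec", seed = "integer"))

setValidity("OctCohort", function(object) {
  n <- nrow(object@patients)
  ok <- function(x) length(x) %in% c(0L, n)   # empty = covariates-only cohort
  if (!ok(object@scans) || !ok(object@annotations))
    return("scans and annotations must be parallel to the patient table")
  TRUE
})

setMethod("show", "OctCohort", function(object) {
  cat(sprintf("OctCohort: %d patients (%d A / %d B), seed %d\n",
              nrow(object@patients), sum(object@patients$group == "A"),
              sum(object@patients$group == "B"), object@seed))
})

#' @describeIn OctCohort clinical patient table
#' @param object an `OctCohort`
#' @export
patientData <- function(object) object@patients

#' @describeIn OctCohort list of rendered B-scans
#' @export
cohortScans <- function(object) object@scans

#' @describeIn OctCohort list of layer annotations
#' @export
cohortAnnotations <- function(object) object@annotations

#' Generate a monthly BCVA series consistent with a prognosis group
#'
#' The series runs from the resolution month through month 12 as a Gaussian
#' random walk with a small monthly drift, reflected into plausible logMAR
#' bounds, starting at the BCVA at first edema resolution.  It is
#' rejection-sampled until [assignGroup()] returns the requested group
#' (good prognosis A: best acuity reaches <= 0 logMAR and acuity never
#' exceeds 0.15 logMAR; B otherwise), with a bounded number of retries.
#'
#' @param group `"A"` or `"B"`.
#' @param bcvaResolution logMAR BCVA at the first resolution of the edema
#'   (the series start).
#' @param resolutionMonth month of first resolution, 1 or 2.
#' @param spec a [CohortSpec-class] supplying the walk parameters.
#' @return Numeric logMAR series of length `13 - resolutionMonth`.
#' @export
generateBcvaSeries <- function(group, bcvaResolution, resolutionMonth = 1L,
                               spec = cohortSpec()) {
  group <- match.arg(group, c("A", "B"))
  stopifnot(resolutionMonth %in% 1:2)
  cl <- spec@clinical
  len <- 13L - as.integer(resolutionMonth)
  lo <- cl$bcvaBounds[1]; hi <- cl$bcvaBounds[2]
  reflect <- function(x) {
    while (x < lo || x > hi) x <- if (x < lo) 2 * lo - x else 2 * hi - x
    x
  }
  for (try in seq_len(cl$maxTries)) {
    s <- numeric(len)
    s[1] <- reflect(bcvaResolution)
    for (t in seq_len(len - 1L))
      s[t + 1L] <- reflect(s[t] + cl$bcvaDrift[[group]] +
                             stats::rnorm(1, 0, cl$bcvaStep[[group]]))
    if (assignGroup(s) == group) return(s)
  }
  stop(sprintf("could not generate a group-%s BCVA series in %d tries from start %.3f",
               group, cl$maxTries, bcvaResolution))
}

.drawTrunc <- function(p) {
  if (identical(p$dist, "lognormal"))
    rtrunclnorm1(1L, p$mean, p$sd, p$lo, p$hi)
  else rtruncnorm1(1L, p$mean, p$sd, p$lo, p$hi)
}

## one or two contiguous absent runs covering ngap of the 50 columns
.gapColumns <- function(ngap) {
  if (ngap <= 0L) return(integer(0))
  nseg <- if (ngap >= 6L && stats::runif(1) < 0.5) 2L else 1L
  sizes <- if (nseg == 2L) {
    a <- sample(seq_len(ngap - 1L), 1L); c(a, ngap - a)
  } else ngap
  cols <- integer(0)
  for (sz in sizes) {
    start <- sample.int(SCAN_COLS - sz + 1L, 1L)
    cols <- union(cols, start:(start + sz - 1L))
  }
  cols
}

#' Render a synthetic trimmed B-scan and its layer annotation
#'
#' Draws three bright bands (ELM, EZ, RPE) as Gaussian depth profiles on a
#' noisy dark background, following smooth row traces with group-dependent
#' brightness, blur, outer-segment spacing and disruption (gap) patterns:
#' Group B eyes have dimmer-contrast, more blurred and more frequently
#' interrupted ELM/EZ bands.  The exact traces used for rendering are
#' returned as the annotation, with `NA` at the disrupted columns.
#'
#' @param group `"A"` or `"B"`.
#' @param spec a [CohortSpec-class].
#' @return A list with elements `scan` ([TrimmedBScan-class]) and
#'   `annotation` ([AnnotationSet-class]).
#' @export
renderLayers <- function(group, spec = cohortSpec()) {
  group <- match.arg(group, c("A", "B"))
  im <- spec@image
  bg <- rtruncnorm1(1L, im$background["mean"], im$background["sd"], 5, 80)
  x <- ((seq_len(SCAN_COLS) - (SCAN_COLS + 1) / 2) / ((SCAN_COLS - 1) / 2))
  curv <- stats::rnorm(1, im$curvature["mean"], im$curvature["sd"])
  rpeRow <- roundHalfUp(rtruncnorm1(1L, im$rpeCenter["mean"], im$rpeCenter["sd"],
                                    140, 200) + curv * x^2)
  dEzRpe <- roundHalfUp(.drawTrunc(as.list(im$ezToRpe[[group]])))
  dElmEz <- roundHalfUp(.drawTrunc(as.list(im$elmToEz[c("mean", "sd", "lo", "hi")])))
  rpeRow <- pmin(pmax(rpeRow, 30L), SCAN_ROWS - 6L)
  ezRow <- rpeRow - dEzRpe
  elmRow <- ezRow - dElmEz

  ## disruption pattern per layer (RPE always intact)
  presence <- list(elm = rep(TRUE, SCAN_COLS), ez = rep(TRUE, SCAN_COLS),
                   rpe = rep(TRUE, SCAN_COLS))
  for (layer in c("elm", "ez")) {
    grade <- sample(0:2, 1L, prob = im$gradeProbs[[layer]][[group]])
    if (grade == 0L) {
      presence[[layer]][] <- FALSE
    } else if (grade == 1L) {
      f <- stats::runif(1, im$grade1PresentRange[1], im$grade1PresentRange[2])
      ngap <- min(max(roundHalfUp(SCAN_COLS * (1 - f)), 3L), SCAN_COLS - 3L)
      presence[[layer]][.gapColumns(ngap)] <- FALSE
    }
  }

  rows <- list(elm = elmRow, ez = ezRow, rpe = rpeRow)
  img <- matrix(0, SCAN_ROWS, SCAN_COLS)
  ax <- seq_len(SCAN_ROWS)
  for (layer in c("elm", "ez", "rpe")) {
    pk <- rtruncnorm1(1L, im[[layer]]$peak[[group]], im[[layer]]$peakSd[[group]],
                      5, 225)
    sg <- rtruncnorm1(1L, im[[layer]]$sigma[[group]], im[[layer]]$sigmaSd[[group]],
                      0.8, 8)
    for (j in which(presence[[layer]]))
      img[, j] <- img[, j] + pk * exp(-((ax - rows[[layer]][j])^2) / (2 * sg^2))
  }
  px <- pmin(pmax(round(img + bg + stats::rnorm(length(img), 0, im$noiseSd)), 0), 255)
  scan <- TrimmedBScan(px)
  naify <- function(r, pres) { r[!pres] <- NA_integer_; as.integer(r) }
  ann <- AnnotationSet(naify(elmRow, presence$elm),
                       naify(ezRow, presence$ez), rpeRow)
  list(scan = scan, annotation = ann)
}

#' Generate a full synthetic cohort
#'
#' Draws `nA + nB` patients with group-conditional clinical covariates,
#' monthly BCVA series that satisfy the prognosis-group definition by
#' construction, and a rendered B-scan with exact layer annotations per
#' eye.  Fully reproducible from the seed.
#'
#' @param spec a [CohortSpec-class].
#' @param seed seed overriding `spec@seed`.
#' @param images render a B-scan per eye (default); `FALSE` gives a fast
#'   covariates-only cohort for large-sample distribution checks.
#' @return An [OctCohort-class].
#' @export
generateCohort <- function(spec = cohortSpec(), seed = NULL, images = TRUE) {
  validObject(spec)
  if (is.null(seed)) seed <- spec@seed
  set.seed(as.integer(seed))
  cl <- spec@clinical
  n <- spec@nA + spec@nB
  groups <- rep(c("A", "B"), c(spec@nA, spec@nB))
  rows <- vector("list", n)
  scans <- vector("list", n)
  anns <- vector("list", n)
  for (i in seq_len(n)) {
    g <- groups[i]
    bcvaRes <- .drawTrunc(cl$bcva_resolution[[g]])
    weeks <- .drawTrunc(cl$resolution_weeks[[g]])
    month <- if (weeks <= 6) 1L else 2L
    series <- generateBcvaSeries(g, bcvaRes, month, spec)
    bcva <- rep(NA_real_, 12L)
    bcva[month:12] <- series
    rows[[i]] <- data.frame(
      id = sprintf("P%03d", i), group = g,
      age = .drawTrunc(cl$age[[g]]),
      sex = if (stats::runif(1) < cl$pMale[[g]]) "male" else "female",
      onset_to_treatment = .drawTrunc(cl$onset_to_treatment[[g]]),
      occlusion_type = if (stats::runif(1) < cl$pMajor[[g]]) "major" else "macular",
      eye = if (stats::runif(1) < cl$pRight[[g]]) "right" else "left",
      semifield = if (stats::runif(1) < cl$pSuperior[[g]]) "superior" else "inferior",
      bcva_baseline = .drawTrunc(cl$bcva_baseline[[g]]),
      bcva_resolution = bcvaRes,
      resolution_weeks = weeks, resolution_month = month,
      n_injections = max(1L, roundHalfUp(.drawTrunc(cl$n_injections[[g]]))))
    rows[[i]] <- cbind(rows[[i]],
                       stats::setNames(as.data.frame(as.list(bcva)),
                                       sprintf("bcva_m%d", 1:12)))
    if (images) {
      r <- renderLayers(g, spec)
      scans[[i]] <- r$scan
      anns[[i]] <- r$annotation
    }
  }
  if (!images) scans <- anns <- list()
  new("OctCohort", patients = do.call(rbind, rows), scans = scans,
      annotations = anns, spec = spec, seed = as.integer(seed))
}

#' Clinical covariates plus extracted image features of a cohort
#'
#' Runs [extractFeatures()] on every scan/annotation pair and binds the
#' seven image features to the clinical covariates; this is the input table
#' of the variable screen ([selectCandidates()]).
#'
#' @param cohort an [OctCohort-class].
#' @return data.frame with one row per patient: `id`, `group`, the clinical
#'   covariates, and the seven image features.
#' @export
cohortFeatures <- function(cohort) {
  stopifnot(is(cohort, "OctCohort"))
  if (length(cohort@scans) == 0L)
    stop("cohort was generated without images; rerun generateCohort(images = TRUE)")
  feats <- do.call(rbind, Map(extractFeatures, cohort@scans, cohort@annotations))
  clin <- cohort@patients[, c("id", "group", "age", "sex", "onset_to_treatment",
                              "occlusion_type", "eye", "semifield",
                              "bcva_baseline", "bcva_resolution",
                              "resolution_weeks")]
  cbind(clin, feats, row.names = NULL)
}
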