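#' Pipeline configuration
#'
#' Bundles every setting of the end-to-end analysis: output location,
#' synthetic-cohort spec, experiment config, screening thresholds and the
#' master seed.  All stage randomness (cohort generation, splits, folds)
#' derives from the master seed through named substreams, so a rerun with
#' the same config is byte-identical.
#'
#' @param outputDir directory receiving all artifacts.
#' @param spec a [CohortSpec-class] for the simulate stage.
#' @param experiment an [experimentConfig()].
#' @param alpha significance level of the variable screen.
#' @param r2Threshold multicollinearity threshold.
#' @param seed master seed.
#' @return A list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(outputDir, spec = cohortSpec(),
                           experiment = experimentConfig(),
                           alpha = 0.05, r2Threshold = 0.9, seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, r2Threshold > 0, r2Threshold < 1)
  structure(list(outputDir = outputDir, spec = spec, experiment = experiment,
                 alpha = alpha, r2Threshold = r2Threshold,
                 seed = as.integer(seed)),
            class = "pipelineConfig")
}

.artifact <- function(config, ...) file.path(config$outputDir, ...)

.needArtifact <- function(config, file, stage) {
  path <- .artifact(config, file)
  if (!file.exists(path))
    stop(sprintf("missing artifact '%s': run stage '%s' first", file, stage))
  path
}

.logStage <- function(stage, t0, what) {
  message(sprintf("[%s] %s (%.2fs)", stage, what,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
}

.writeJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

.designFromFeatures <- function(feat, retained) {
  X <- as.matrix(data.frame(lapply(feat[retained], asNumericCovariate)))
  colnames(X) <- retained
  y <- as.numeric(feat$group == "B")
  list(X = X, y = y)
}

#' Run the prognosis-classification pipeline
#'
#' Executes the requested stages in order: `simulate` (generate the
#' synthetic cohort: cohort CSV, per-eye PNG + annotation CSV, manifest),
#' `extract` (read the images and annotations back from disk and compute
#' the seven handcrafted features into `features.csv`), `select` (variable
#' screen + multicollinearity elimination into `screen.json`), `train`
#' (stage-1 repeated grid search into `stage1.json`), `evaluate` (stage-2
#' repeated evaluation at the modal C into `stage2.json`), and `report`
#' (consolidated `report.json`).  `"all"` runs everything.  Each stage
#' logs one line with its timing, requires its upstream artifacts, and is
#' reproducible from the master seed.
#'
#' @param config a [pipelineConfig()].
#' @param stages character vector of stages, or `"all"`.
#' @return Invisibly, the path of the last artifact written.
#' @export
runPipeline <- function(config, stages = "all") {
  allStages <- c("simulate", "extract", "select", "train", "evaluate", "report")
  if (identical(stages, "all")) stages <- allStages
  stages <- match.arg(stages, allStages, several.ok = TRUE)
  dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
  last <- NULL

  if ("simulate" %in% stages) {
    t0 <- Sys.time()
    cohort <- generateCohort(config$spec, seed = substreamSeed(config$seed, 10L))
    utils::write.csv(cohort@patients, .artifact(config, "cohort.csv"),
                     row.names = FALSE, na = "")
    dir.create(.artifact(config, "images"), showWarnings = FALSE)
    dir.create(.artifact(config, "annotations"), showWarnings = FALSE)
    for (i in seq_len(nrow(cohort@patients))) {
      id <- cohort@patients$id[i]
      writeBScan(cohort@scans[[i]], .artifact(config, "images", paste0(id, ".png")))
      writeAnnotation(cohort@annotations[[i]],
                      .artifact(config, "annotations", paste0(id, ".csv")))
    }
    .writeJson(list(seed = config$seed, nA = config$spec@nA, nB = config$spec@nB,
                    n = nrow(cohort@patients)),
               .artifact(config, "manifest.json"))
    .logStage("simulate", t0, sprintf("%d patients written", nrow(cohort@patients)))
    last <- .artifact(config, "manifest.json")
  }

  if ("extract" %in% stages) {
    t0 <- Sys.time()
    cohortCsv <- .needArtifact(config, "cohort.csv", "simulate")
    patients <- utils::read.csv(cohortCsv)
    feats <- do.call(rbind, lapply(patients$id, function(id) {
      img <- readBScan(.needArtifact(config, file.path("images", paste0(id, ".png")),
                                     "simulate"))
      ann <- readAnnotation(.needArtifact(config,
                                          file.path("annotations", paste0(id, ".csv")),
                                          "simulate"))
      cbind(id = id, extractFeatures(img, ann))
    }))
    utils::write.csv(feats, .artifact(config, "features.csv"), row.names = FALSE)
    .logStage("extract", t0, sprintf("%d feature rows", nrow(feats)))
    last <- .artifact(config, "features.csv")
  }

  if ("select" %in% stages) {
    t0 <- Sys.time()
    patients <- utils::read.csv(.needArtifact(config, "cohort.csv", "simulate"))
    feats <- utils::read.csv(.needArtifact(config, "features.csv", "extract"))
    tab <- merge(patients[, c("id", "group", "age", "sex", "onset_to_treatment",
                              "occlusion_type", "eye", "semifield",
                              "bcva_baseline", "bcva_resolution",
                              "resolution_weeks")],
                 feats, by = "id")
    screen <- selectCandidates(tab, alpha = config$alpha,
                               r2Threshold = config$r2Threshold)
    ## paired baseline-vs-12-month acuity comparison across the cohort
    pPaired <- wilcoxonSignedRank(patients$bcva_baseline, patients$bcva_m12)
    .writeJson(list(screen = screen@screen,
                    retained = as.list(screen@retained),
                    r2 = as.list(screen@r2),
                    wilcoxon_baseline_vs_12m_p = pPaired,
                    alpha = config$alpha, r2Threshold = config$r2Threshold),
               .artifact(config, "screen.json"))
    .logStage("select", t0, sprintf("%d retained of %d candidates",
                                    length(screen@retained), nrow(screen@screen)))
    last <- .artifact(config, "screen.json")
  }

  if (any(c("train", "evaluate", "report") %in% stages)) {
    screenPath <- .needArtifact(config, "screen.json", "select")
    retained <- unlist(jsonlite::read_json(screenPath)$retained)
    patients <- utils::read.csv(.needArtifact(config, "cohort.csv", "simulate"))
    feats <- utils::read.csv(.needArtifact(config, "features.csv", "extract"))
    tab <- merge(patients, feats, by = "id")
    d <- .designFromFeatures(tab, retained)
    wGroupA <- sum(d$y == 1) / sum(d$y == 0)
    cfg <- config$experiment
    cfg$seed <- substreamSeed(config$seed, 20L)
  }

  if ("train" %in% stages) {
    t0 <- Sys.time()
    s1 <- stage1(d$X, d$y, cfg, w0 = 1, w1 = wGroupA)
    .writeJson(list(frequency = as.list(s1$frequency), modalC = s1$modalC),
               .artifact(config, "stage1.json"))
    .logStage("train", t0, sprintf("modal C = %g", s1$modalC))
    last <- .artifact(config, "stage1.json")
  }

  if ("evaluate" %in% stages) {
    t0 <- Sys.time()
    modalC <- jsonlite::read_json(.needArtifact(config, "stage1.json", "train"))$modalC
    res <- stage2(d$X, d$y, modalC, cfg, w0 = 1, w1 = wGroupA)
    s <- aucSummary(res)
    .writeJson(list(C = modalC, aucMean = s[["mean"]], aucSd = s[["sd"]],
                    aucValues = res@aucValues,
                    coefficients = coefficientTable(res)),
               .artifact(config, "stage2.json"))
    .logStage("evaluate", t0, sprintf("AUC %.3f +/- %.3f", s[["mean"]], s[["sd"]]))
    last <- .artifact(config, "stage2.json")
  }

  if ("report" %in% stages) {
    t0 <- Sys.time()
    screen <- jsonlite::read_json(.needArtifact(config, "screen.json", "select"))
    s1 <- jsonlite::read_json(.needArtifact(config, "stage1.json", "train"))
    s2 <- jsonlite::read_json(.needArtifact(config, "stage2.json", "evaluate"))
    report <- list(seed = config$seed,
                   configHash = sprintf("%08x", sum(utf8ToInt(paste(
                     config$seed, config$alpha, config$r2Threshold,
                     config$experiment$nRepeats, collapse = ":")))),
                   nPatients = length(utils::read.csv(
                     .needArtifact(config, "cohort.csv", "simulate"))$id),
                   screen = screen, stage1 = s1, stage2 = s2)
    .writeJson(report, .artifact(config, "report.json"))
    .logStage("report", t0, "report.json written")
    last <- .artifact(config, "report.json")
  }
  invisible(last)
}
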