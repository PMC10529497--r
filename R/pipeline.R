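# End-to-end orchestration: config-driven simulate -> extract -> fit ->
# evaluate -> select runs with standard-format outputs and an audit log.

.CONFIG_DEFAULTS <- list(
    mode = "synthetic",          # "synthetic" | "manifest"
    nCases = 50L,
    regions = "L1",
    seed = 1L,
    boneFractionRange = c(0.15, 0.55),
    bmdFloorRate = 0,
    missingRate = 0,
    targetR = 0.65,
    phantom = list(),            # overrides passed to phantomParams()
    manifest = NULL,             # directory with manifest.csv
    roiMode = "manifest",        # "manifest" | "auto" | "full"
    thresholdLow = 100,
    thresholdHigh = 500,
    levels = c(16L, 32L, 64L, 128L),
    orientations = c("horizontal", "vertical"),
    statistics = c("entropy", "contrast", "correlation", "homogeneity",
                   "variance"),
    protocol = "full",           # "full" | "split"
    splitFraction = 0.8,
    targets = NULL,              # default: all targets of the cohort
    outputDir = NULL,
    writeImages = FALSE,
    imageFormat = "csv",
    logLevel = "info")

#' Build a validated pipeline configuration
#'
#' Named arguments override the defaults below; unknown keys are
#' rejected. The same keys can be stored in a YAML file and loaded with
#' [readRunConfig()].
#'
#' \describe{
#'   \item{mode}{"synthetic" (generate a phantom cohort) or "manifest"
#'     (read images + manifest from \code{manifest}).}
#'   \item{nCases, regions, seed, boneFractionRange, bmdFloorRate,
#'     missingRate, targetR, phantom}{cohort generation; \code{phantom}
#'     is a list of [phantomParams()] overrides.}
#'   \item{roiMode}{"manifest" (rectangles from the manifest / full grid),
#'     "auto" (HU-band threshold + largest component + maximal inscribed
#'     rectangle), or "full" (whole image).}
#'   \item{thresholdLow, thresholdHigh}{HU band for \code{roiMode =
#'     "auto"}.}
#'   \item{levels, orientations, statistics}{GLCM configuration.}
#'   \item{protocol}{"full" (fit and evaluate on the whole filtered
#'     cohort) or "split" (train on \code{splitFraction}, evaluate on the
#'     held-out remainder; split drawn from \code{seed}).}
#'   \item{targets}{target subset; default all.}
#'   \item{outputDir}{where artifacts are written (required by
#'     [runPipeline()]).}
#'   \item{writeImages, imageFormat}{also write the cohort images and
#'     manifest ("csv" grids or 16-bit "tiff").}
#' }
#'
#' @param ... configuration overrides.
#' @return A validated config list (class \code{"boneTextureConfig"}).
#' @examples
#' cfg <- runConfig(nCases = 20, seed = 3, outputDir = tempfile())
#' @export
runConfig <- function(...) {
    override <- list(...)
    if (length(override) && is.null(names(override)))
        stop("configuration values must be named")
    unknown <- setdiff(names(override), names(.CONFIG_DEFAULTS))
    if (length(unknown))
        stop("unknown configuration key(s): ",
             paste(unknown, collapse = ", "))
    cfg <- .CONFIG_DEFAULTS
    cfg[names(override)] <- override
    if (!cfg$mode %in% c("synthetic", "manifest"))
        stop("mode must be 'synthetic' or 'manifest'")
    if (!cfg$roiMode %in% c("manifest", "auto", "full"))
        stop("roiMode must be 'manifest', 'auto' or 'full'")
    if (!cfg$protocol %in% c("full", "split"))
        stop("protocol must be 'full' or 'split'")
    if (cfg$mode == "manifest" && is.null(cfg$manifest))
        stop("manifest mode requires the 'manifest' directory")
    if (cfg$protocol == "split" &&
        !(cfg$splitFraction > 0 && cfg$splitFraction < 1))
        stop("splitFraction must be in (0, 1)")
    cfg$nCases <- as.integer(cfg$nCases)
    cfg$seed <- as.integer(cfg$seed)
    cfg$levels <- as.integer(cfg$levels)
    structure(cfg, class = "boneTextureConfig")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with [runConfig()] keys.
#' @return A validated config list.
#' @export
readRunConfig <- function(path) {
    do.call(runConfig, yaml::read_yaml(path))
}

.cohortFromConfig <- function(cfg) {
    if (cfg$mode == "manifest") return(readCohort(cfg$manifest))
    phantom <- do.call(phantomParams, cfg$phantom)
    spec <- cohortSpec(nCases = cfg$nCases, regions = cfg$regions,
                       targetModel = defaultTargetModel(
                           cfg$targetR, cfg$boneFractionRange),
                       boneFractionRange = cfg$boneFractionRange,
                       bmdFloorRate = cfg$bmdFloorRate,
                       missingRate = cfg$missingRate,
                       phantom = phantom, seed = cfg$seed)
    generateCohort(spec)
}

.roisFromConfig <- function(cfg, cohort) {
    df <- cohort@data
    n <- nrow(df)
    if (cfg$roiMode == "manifest" &&
        all(c("row0", "col0", "height", "width") %in% colnames(df)))
        return(as.data.frame(df[c("row0", "col0", "height", "width")]))
    if (cfg$roiMode == "auto") {
        out <- data.frame(row0 = integer(n), col0 = integer(n),
                          height = integer(n), width = integer(n))
        for (i in seq_len(n)) {
            mask <- thresholdTrabecular(cohort@images[[i]],
                                        cfg$thresholdLow,
                                        cfg$thresholdHigh)
            r <- selectRectangle(mask)
            out[i, ] <- c(r@row0, r@col0, r@height, r@width)
        }
        return(out)
    }
    # "full" (and "manifest" without ROI columns): whole image
    data.frame(row0 = 0L, col0 = 0L,
               height = vapply(cohort@images, nrow, integer(1)),
               width = vapply(cohort@images, ncol, integer(1)))
}

#' Run the full estimation pipeline
#'
#' Orchestrates cohort acquisition (synthetic or manifest), ROI
#' selection, feature extraction, per-target exclusion + fit +
#' evaluation, and correlation-based feature selection. Writes under
#' \code{cfg$outputDir}:
#' \itemize{
#'   \item \code{features.csv} - one row per (case, region), 45 named
#'     feature columns;
#'   \item \code{models/model_<target>.json} - serialised
#'     [BMDModel-class] per target;
#'   \item \code{evaluation.csv} - one row per target: \code{target, cc,
#'     mse, n};
#'   \item \code{selection_correlations.csv},
#'     \code{selection_counts.csv} - feature ranking tables;
#'   \item \code{run_log.txt} - package version, seed, configuration
#'     digest and the per-target case-exclusion audit.
#' }
#' All outputs are derived from config + seed alone; rerunning with the
#' same configuration gives byte-identical files.
#'
#' @param cfg a config from [runConfig()] / [readRunConfig()].
#' @return Invisibly, a list: \code{evaluation} (data.frame),
#'   \code{selection} ([SelectionResult-class]), \code{models} (named
#'   list of [BMDModel-class]), \code{exclusions} (named list of audit
#'   logs), \code{paths} (named artifact paths).
#' @examples
#' cfg <- runConfig(nCases = 12, seed = 5, outputDir = tempfile())
#' rep <- runPipeline(cfg)
#' rep$evaluation
#' @export
runPipeline <- function(cfg) {
    if (!inherits(cfg, "boneTextureConfig"))
        cfg <- do.call(runConfig, as.list(cfg))
    if (is.null(cfg$outputDir))
        stop("outputDir is required")
    dir.create(cfg$outputDir, recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(cfg$outputDir, "models"), showWarnings = FALSE)

    cohort <- tryCatch(.cohortFromConfig(cfg),
                       error = function(e) stop("cohort stage: ",
                                                conditionMessage(e)))
    if (isTRUE(cfg$writeImages) && cfg$mode == "synthetic")
        writeCohort(cohort, file.path(cfg$outputDir, "cohort"),
                    format = cfg$imageFormat)

    rois <- tryCatch(.roisFromConfig(cfg, cohort),
                     error = function(e) stop("roi stage: ",
                                              conditionMessage(e)))
    te <- tryCatch(
        extractFeatures(cohort, rois = rois, levels = cfg$levels,
                        orientations = cfg$orientations,
                        statistics = cfg$statistics),
        error = function(e) stop("feature stage: ", conditionMessage(e)))
    paths <- c(features = file.path(cfg$outputDir, "features.csv"))
    writeFeatureTable(te, paths[["features"]])

    targets <- if (is.null(cfg$targets)) targetNames(te) else cfg$targets
    missingT <- setdiff(targets, colnames(colData(te)))
    if (length(missingT))
        stop("target column(s) not in manifest: ",
             paste(missingT, collapse = ", "))

    evalRows <- list(); models <- list(); exclusions <- list()
    for (t in targets) {
        fit <- tryCatch(.fitTarget(te, t, cfg),
                        error = function(e) stop("regression stage (", t,
                                                 "): ",
                                                 conditionMessage(e)))
        models[[t]] <- fit$model
        exclusions[[t]] <- fit$exclusionLog
        evalRows[[t]] <- fit$evaluation
        writeBMDModel(fit$model,
                      file.path(cfg$outputDir, "models",
                                paste0("model_", t, ".json")))
    }
    evaluation <- do.call(rbind, evalRows)
    rownames(evaluation) <- NULL
    paths[["evaluation"]] <- file.path(cfg$outputDir, "evaluation.csv")
    utils::write.csv(evaluation, paths[["evaluation"]], row.names = FALSE)

    sel <- selectFeatures(te, targets = targets)
    selPaths <- writeSelection(sel, file.path(cfg$outputDir, "selection"))
    paths <- c(paths, selPaths)

    paths[["log"]] <- file.path(cfg$outputDir, "run_log.txt")
    .writeRunLog(paths[["log"]], cfg, te, targets, exclusions, evaluation)

    invisible(list(evaluation = evaluation, selection = sel,
                   models = models, exclusions = exclusions,
                   paths = paths))
}

# per-target fit honouring the evaluation protocol
.fitTarget <- function(te, target, cfg) {
    ex <- excludeCases(te, target)
    teF <- ex$experiment
    if (cfg$protocol == "split") {
        n <- ncol(teF)
        nTrain <- max(2L, round(cfg$splitFraction * n))
        if (nTrain >= n)
            stop("split leaves no evaluation cases (n = ", n, ")")
        trainIdx <- withr::with_seed(cfg$seed,
                                     sort(sample.int(n, nTrain)))
        teTrain <- teF[, trainIdx]
        teTest <- teF[, -trainIdx]
    } else {
        teTrain <- teF
        teTest <- teF
    }
    X <- featureMatrix(teTrain)
    y <- colData(teTrain)[[target]]
    nm <- normalizeFeatures(X, y)
    fit <- fitLinearModel(nm$X, nm$y)
    weights <- setNames(numeric(ncol(X)), colnames(X))
    weights[names(fit$weights)] <- fit$weights
    model <- new("BMDModel", bias = fit$bias, weights = weights,
                 featureMeans = nm$featureMeans,
                 featureSds = nm$featureSds,
                 targetMean = nm$targetMean, targetSd = nm$targetSd,
                 targetName = target, dropped = nm$dropped)
    list(model = model, exclusionLog = ex$log,
         evaluation = evaluateModel(model, teTest))
}

.writeRunLog <- function(path, cfg, te, targets, exclusions, evaluation) {
    con <- file(path, open = "wt")
    on.exit(close(con))
    w <- function(...) writeLines(sprintf(...), con)
    w("boneTexture run log")
    w("package version: %s", as.character(utils::packageVersion("boneTexture")))
    w("seed: %d", cfg$seed)
    w("mode: %s | roiMode: %s | protocol: %s", cfg$mode, cfg$roiMode,
      cfg$protocol)
    w("samples extracted: %d (features: %d)", ncol(te),
      nrow(assay(te, "features")))
    for (t in targets) {
        log <- exclusions[[t]]
        kept <- evaluation$n[evaluation$target == t]
        w("target %s: excluded %d, evaluated on %d (extracted %d)",
          t, nrow(log), kept, ncol(te))
        if (nrow(log))
            for (i in seq_len(nrow(log)))
                w("  excluded %s/%s: %s", log$caseId[i], log$region[i],
                  log$reason[i])
    }
}
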