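# Synthetic cohort generation and cohort I/O.

#' Generate a synthetic cohort
#'
#' Draws a latent bone fraction per case (uniform on
#' \code{spec@boneFractionRange}), derives the eight DXA-like reference
#' targets via the per-target affine map plus Gaussian noise, and renders
#' one phantom image per (case, region). All randomness flows from
#' \code{spec@seed}: phantom images use per-row seeds drawn once from the
#' cohort stream, so the cohort is reproducible as a whole and row images
#' do not share state.
#'
#' Construction guarantees used by the exclusion-rule machinery:
#' \itemize{
#'   \item exactly \code{round(bmdFloorRate * nCases)} cases have all
#'     their BMD-type targets in [0.05, 0.149), i.e. below the 0.15
#'     screening cutoff; all other cases have BMD targets >= 0.15 (values
#'     that would cross the cutoff by noise are reflected about it);
#'   \item exactly \code{round(missingRate * nCases)} cases carry a
#'     \code{missingFeature} index (one withheld feature value, applied at
#'     extraction time).
#' }
#'
#' @param spec a [CohortSpec-class].
#' @param images logical; \code{FALSE} skips phantom rendering (targets
#'   and latent drivers only), which is much faster when only the target
#'   model is under study. The image seeds are drawn either way, so the
#'   realised targets are identical across the two modes.
#' @return A [BoneCohort-class]; one row per (case, region).
#' @examples
#' coh <- generateCohort(cohortSpec(nCases = 5, regions = "L1", seed = 2))
#' cohortData(coh)
#' @export
generateCohort <- function(spec, images = TRUE) {
    stopifnot(is(spec, "CohortSpec"))
    validObject(spec)
    withr::with_seed(spec@seed, .cohortImpl(spec, images))
}

.cohortImpl <- function(spec, images) {
    n <- spec@nCases
    regions <- spec@regions
    tm <- spec@targetModel
    rng <- spec@boneFractionRange

    f <- stats::runif(n, rng[1], rng[2])
    nFloor <- round(spec@bmdFloorRate * n)
    floorIdx <- if (nFloor > 0) sample.int(n, nFloor) else integer(0)

    targets <- matrix(NA_real_, n, nrow(tm),
                      dimnames = list(NULL, tm$target))
    for (t in seq_len(nrow(tm))) {
        y <- tm$intercept[t] + tm$slope[t] * f +
            stats::rnorm(n, 0, tm$noiseSd[t])
        if (tm$type[t] == "bmd") {
            low <- setdiff(which(y < 0.15), floorIdx)
            y[low] <- 0.30 - y[low]          # reflect above the cutoff
            if (nFloor > 0)
                y[floorIdx] <- stats::runif(nFloor, 0.05, 0.149)
        }
        targets[, t] <- y
    }

    nMiss <- round(spec@missingRate * n)
    missingFeature <- rep(NA_integer_, n)
    if (nMiss > 0) {
        missIdx <- sample.int(n, nMiss)
        missingFeature[missIdx] <- sample.int(45L, nMiss, replace = TRUE)
    }

    nRows <- n * length(regions)
    caseIdx <- rep(seq_len(n), each = length(regions))
    imageSeeds <- sample.int(2147483646L, nRows)

    imgs <- list()
    if (images) {
        tmpl <- spec@phantom
        imgs <- vector("list", nRows)
        for (i in seq_len(nRows)) {
            p <- tmpl
            p@boneFraction <- f[caseIdx[i]]
            p@seed <- imageSeeds[i]
            imgs[[i]] <- .phantomImpl2(p)
        }
    }

    df <- DataFrame(
        caseId = sprintf("case_%04d", caseIdx),
        region = rep(regions, times = n),
        boneFraction = f[caseIdx],
        missingFeature = missingFeature[caseIdx])
    for (t in colnames(targets)) df[[t]] <- targets[caseIdx, t]

    new("BoneCohort", images = imgs, data = df,
        meta = list(spec = spec, imageSeeds = imageSeeds))
}

# seeded phantom without the validity/seed-restore overhead of the
# exported generatePhantom (called in a tight loop)
.phantomImpl2 <- function(params) {
    withr::with_seed(params@seed, .phantomImpl(params))
}

# HU <-> 16-bit intensity mapping for TIFF storage: stored = (HU + 1024)
# on a 0..65535 scale. Documented so files are interpretable standalone.
.HU_OFFSET <- 1024
.huToIntensity <- function(hu) {
    pmin(pmax((hu + .HU_OFFSET) / 65535, 0), 1)
}
.intensityToHU <- function(v) v * 65535 - .HU_OFFSET

#' Write a cohort to disk
#'
#' Writes one image file per (case, region) under \code{dir/images/} and a
#' \code{manifest.csv} with columns \code{case_id, region, image_path,
#' bone_fraction, <one column per target>, missing_feature, row0, col0,
#' height, width}. ROI columns describe the rectangle to analyse (for
#' synthetic phantoms, the full grid). Images are plain CSV grids of HU
#' values (lossless, default) or 16-bit grayscale TIFF with intensity =
#' (HU + 1024)/65535, i.e. a stored offset of 1024 HU and ~1 HU
#' quantisation.
#'
#' @param cohort a [BoneCohort-class] with images.
#' @param dir output directory (created if needed).
#' @param format "csv" or "tiff".
#' @return The manifest path, invisibly.
#' @export
writeCohort <- function(cohort, dir, format = c("csv", "tiff")) {
    format <- match.arg(format)
    stopifnot(is(cohort, "BoneCohort"))
    if (!length(cohort@images))
        stop("cohort has no images to write")
    dir.create(file.path(dir, "images"), recursive = TRUE,
               showWarnings = FALSE)
    df <- as.data.frame(cohort@data)
    ext <- if (format == "csv") "csv" else "tif"
    paths <- sprintf("images/%s_%s.%s", df$caseId, df$region, ext)
    for (i in seq_len(nrow(df))) {
        img <- cohort@images[[i]]
        fp <- file.path(dir, paths[i])
        if (format == "csv") {
            utils::write.table(img, fp, sep = ",", row.names = FALSE,
                               col.names = FALSE)
        } else {
            tiff::writeTIFF(.huToIntensity(img), fp, bits.per.sample = 16L)
        }
    }
    tn <- targetNames(cohort)
    man <- data.frame(case_id = df$caseId, region = df$region,
                      image_path = paths,
                      bone_fraction = df$boneFraction,
                      stringsAsFactors = FALSE)
    for (t in tn) man[[t]] <- df[[t]]
    man$missing_feature <- df$missingFeature
    man$row0 <- 0L
    man$col0 <- 0L
    man$height <- vapply(cohort@images, nrow, integer(1))
    man$width <- vapply(cohort@images, ncol, integer(1))
    manPath <- file.path(dir, "manifest.csv")
    utils::write.csv(man, manPath, row.names = FALSE)
    invisible(manPath)
}

#' Read a cohort from a manifest directory
#'
#' Reads a directory produced by [writeCohort()] (or hand-built to the
#' same schema: \code{manifest.csv} plus image files, CSV grids or 16-bit
#' TIFF). Errors name the offending case and path when an image file is
#' missing.
#'
#' @param dir directory containing \code{manifest.csv}.
#' @return A [BoneCohort-class].
#' @export
readCohort <- function(dir) {
    manPath <- file.path(dir, "manifest.csv")
    if (!file.exists(manPath))
        stop("no manifest.csv in ", dir)
    man <- utils::read.csv(manPath, stringsAsFactors = FALSE)
    need <- c("case_id", "region", "image_path")
    if (!all(need %in% names(man)))
        stop("manifest must have columns ", paste(need, collapse = ", "))
    imgs <- vector("list", nrow(man))
    for (i in seq_len(nrow(man))) {
        fp <- file.path(dir, man$image_path[i])
        if (!file.exists(fp))
            stop(sprintf("missing image file for case %s (%s): %s",
                         man$case_id[i], man$region[i], fp))
        imgs[[i]] <- if (grepl("\\.csv$", fp, ignore.case = TRUE)) {
            as.matrix(utils::read.csv(fp, header = FALSE))
        } else {
            .intensityToHU(tiff::readTIFF(fp))
        }
        dimnames(imgs[[i]]) <- NULL
    }
    fixed <- c("case_id", "region", "image_path", "bone_fraction",
               "missing_feature", "row0", "col0", "height", "width")
    tn <- setdiff(names(man), fixed)
    df <- DataFrame(caseId = man$case_id, region = man$region,
                    boneFraction = if ("bone_fraction" %in% names(man))
                        man$bone_fraction else NA_real_,
                    missingFeature = if ("missing_feature" %in% names(man))
                        as.integer(man$missing_feature) else NA_integer_)
    for (t in tn) df[[t]] <- man[[t]]
    roiCols <- c("row0", "col0", "height", "width")
    if (all(roiCols %in% names(man)))
        for (rc in roiCols) df[[rc]] <- as.integer(man[[rc]])
    new("BoneCohort", images = imgs, data = df,
        meta = list(manifest = manPath, targetNames = tn))
}
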