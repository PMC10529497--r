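# S4 classes for the central data objects. Constructors with validity live
# next to each class; user code should use the lower-case constructor
# functions, never new() directly.

#' Phantom parameters for the synthetic trabecular texture generator
#'
#' Parameters of a single 2D trabecular-bone phantom: a Gaussian random
#' field with a stated correlation length is thresholded at the
#' \code{boneFraction} quantile to obtain a "strut" mask, the two classes
#' get Gaussian HU values, and the result is optionally blurred.
#'
#' @slot gridSize integer(2), image rows and columns (each >= 8).
#' @slot correlationLength positive real, texture scale in pixels.
#' @slot boneFraction real in (0, 1), areal fraction of bone-class pixels.
#' @slot boneHUMean,boneHUSd bone-class HU mean and sd (sd >= 0).
#' @slot marrowHUMean,marrowHUSd marrow-class HU mean and sd (sd >= 0);
#'   \code{boneHUMean} must exceed \code{marrowHUMean}.
#' @slot blurSigma nonnegative real, Gaussian blur sd in pixels.
#' @slot seed integer seed; identical parameters give identical phantoms.
#'
#' @seealso [phantomParams()], [generatePhantom()]
#' @exportClass PhantomParams
setClass("PhantomParams", representation(
    gridSize = "integer",
    correlationLength = "numeric",
    boneFraction = "numeric",
    boneHUMean = "numeric",
    boneHUSd = "numeric",
    marrowHUMean = "numeric",
    marrowHUSd = "numeric",
    blurSigma = "numeric",
    seed = "integer"))

setValidity("PhantomParams", function(object) {
    msg <- character(0)
    if (length(object@gridSize) != 2L || any(is.na(object@gridSize)))
        msg <- c(msg, "gridSize must be two integers")
    else if (any(object@gridSize < 8L))
        msg <- c(msg, "gridSize must be at least 8x8 (too small for GLCM statistics)")
    if (!(object@boneFraction > 0 && object@boneFraction < 1))
        msg <- c(msg, "boneFraction must be strictly between 0 and 1")
    if (object@boneHUMean <= object@marrowHUMean)
        msg <- c(msg, "boneHUMean must exceed marrowHUMean")
    if (object@boneHUSd < 0 || object@marrowHUSd < 0)
        msg <- c(msg, "HU standard deviations must be nonnegative")
    if (object@blurSigma < 0)
        msg <- c(msg, "blurSigma must be nonnegative")
    if (object@correlationLength <= 0)
        msg <- c(msg, "correlationLength must be positive")
    if (length(msg)) msg else TRUE
})

#' Construct phantom parameters
#'
#' Defaults describe a 64x64 trabecular ROI: struts at ~400 HU over marrow
#' at ~50 HU (typical cancellous-bone attenuation), bone areal fraction
#' 0.35, correlation length 3 px, and a light 0.5 px partial-volume blur.
#'
#' @param gridSize integer(2), rows and columns, each >= 8.
#' @param correlationLength texture scale of the underlying random field
#'   (pixels).
#' @param boneFraction target areal fraction of bone-class pixels, in
#'   (0, 1).
#' @param boneHUMean,boneHUSd HU distribution of the bone class.
#' @param marrowHUMean,marrowHUSd HU distribution of the marrow class.
#' @param blurSigma Gaussian blur sd (pixels); 0 disables blurring.
#' @param seed integer seed.
#' @return A [PhantomParams-class] object.
#' @examples
#' p <- phantomParams(boneFraction = 0.25, seed = 7)
#' img <- generatePhantom(p)
#' @export
phantomParams <- function(gridSize = c(64L, 64L), correlationLength = 3,
                          boneFraction = 0.35, boneHUMean = 400,
                          boneHUSd = 50, marrowHUMean = 50, marrowHUSd = 30,
                          blurSigma = 0.5, seed = 1L) {
    new("PhantomParams", gridSize = as.integer(gridSize),
        correlationLength = as.numeric(correlationLength),
        boneFraction = as.numeric(boneFraction),
        boneHUMean = as.numeric(boneHUMean), boneHUSd = as.numeric(boneHUSd),
        marrowHUMean = as.numeric(marrowHUMean),
        marrowHUSd = as.numeric(marrowHUSd),
        blurSigma = as.numeric(blurSigma), seed = as.integer(seed))
}

setMethod("show", "PhantomParams", function(object) {
    cat(sprintf("PhantomParams %dx%d, bone fraction %.3f, HU %g/%g (bone/marrow), blur %g, seed %d\n",
                object@gridSize[1], object@gridSize[2], object@boneFraction,
                object@boneHUMean, object@marrowHUMean, object@blurSigma,
                object@seed))
})

#' Specification of a synthetic cohort
#'
#' Describes a cohort of cases, each with one phantom image per anatomical
#' region and eight DXA-like reference targets driven by a per-case latent
#' bone fraction. See [cohortSpec()] for field semantics.
#'
#' @slot nCases number of cases.
#' @slot regions character vector of region labels.
#' @slot targetModel data.frame with columns \code{target},
#'   \code{intercept}, \code{slope}, \code{noiseSd}, \code{type}
#'   ("bmd"/"bmc"): each target is
#'   \code{intercept + slope * boneFraction + N(0, noiseSd)}.
#' @slot boneFractionRange numeric(2), support of the latent uniform
#'   bone-fraction distribution.
#' @slot bmdFloorRate fraction of cases forced below the 0.15 BMD
#'   exclusion cutoff.
#' @slot missingRate fraction of cases with one feature value withheld.
#' @slot phantom [PhantomParams-class] template for the per-row images.
#' @slot seed integer seed for the whole cohort.
#' @exportClass CohortSpec
setClass("CohortSpec", representation(
    nCases = "integer",
    regions = "character",
    targetModel = "data.frame",
    boneFractionRange = "numeric",
    bmdFloorRate = "numeric",
    missingRate = "numeric",
    phantom = "PhantomParams",
    seed = "integer"))

setValidity("CohortSpec", function(object) {
    msg <- character(0)
    if (length(object@nCases) != 1L || is.na(object@nCases) ||
        object@nCases < 1L)
        msg <- c(msg, "nCases must be a positive integer")
    if (length(object@regions) == 0L)
        msg <- c(msg, "region list must not be empty")
    if (anyDuplicated(object@regions))
        msg <- c(msg, "region labels must be unique")
    tm <- object@targetModel
    need <- c("target", "intercept", "slope", "noiseSd", "type")
    if (!all(need %in% names(tm)))
        msg <- c(msg, paste("targetModel must have columns",
                            paste(need, collapse = ", ")))
    else {
        if (any(tm$noiseSd < 0))
            msg <- c(msg, "target noise sd must be nonnegative")
        if (!all(tm$type %in% c("bmd", "bmc")))
            msg <- c(msg, "target type must be 'bmd' or 'bmc'")
        if (anyDuplicated(tm$target))
            msg <- c(msg, "target names must be unique")
    }
    r <- object@boneFractionRange
    if (length(r) != 2L || r[1] >= r[2] || r[1] <= 0 || r[2] >= 1)
        msg <- c(msg, "boneFractionRange must be an increasing pair within (0, 1)")
    for (nm in c("bmdFloorRate", "missingRate")) {
        v <- slot(object, nm)
        if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
            msg <- c(msg, paste(nm, "must be in [0, 1]"))
    }
    if (length(msg)) msg else TRUE
})

#' Default anatomical region labels
#'
#' Lumbar vertebrae L1-L5, first sacral vertebra, and bilateral femoral
#' neck, intertrochanteric and acetabular regions - the axial-cut regions
#' typically annotated on abdomen/pelvis CT for opportunistic screening.
#'
#' @return character(12) of region labels.
#' @export
defaultRegions <- function() {
    c("L1", "L2", "L3", "L4", "L5", "S1",
      "femur_neck_R", "femur_neck_L",
      "intertroch_R", "intertroch_L",
      "acetabulum_R", "acetabulum_L")
}

#' Default DXA-like target model
#'
#' Affine maps from the latent bone fraction to the eight reference
#' targets (four BMD in g/cm2, four BMC in g), with Gaussian noise
#' calibrated so that the population correlation between the latent driver
#' and each target equals \code{r}. For a driver uniform on
#' \code{boneFractionRange} the required noise sd is
#' \code{|slope| * sd(driver) * sqrt(1/r^2 - 1)}.
#'
#' Intercepts and slopes are fixed design choices that place target values
#' on clinical DXA scales (e.g. total lumbar BMD ~0.6-1.3 g/cm2, total
#' lumbar BMC ~35-65 g) over the default driver range.
#'
#' @param r population driver-target Pearson correlation, in (0, 1].
#' @param boneFractionRange support of the uniform latent driver.
#' @return data.frame with columns \code{target}, \code{intercept},
#'   \code{slope}, \code{noiseSd}, \code{type}.
#' @export
defaultTargetModel <- function(r = 0.65, boneFractionRange = c(0.15, 0.55)) {
    stopifnot(r > 0, r <= 1)
    tm <- data.frame(
        target = c("total_lumbar_bmd", "total_lumbar_bmc",
                   "total_femur_bmd", "total_femur_bmc",
                   "femur_neck_bmd", "femur_neck_bmc",
                   "femur_intertroch_bmd", "femur_intertroch_bmc"),
        intercept = c(0.30, 25, 0.35, 18, 0.30, 2.0, 0.35, 8),
        slope     = c(1.80, 75, 1.60, 45, 1.50, 7.5, 1.70, 25),
        type = rep(c("bmd", "bmc"), 4),
        stringsAsFactors = FALSE)
    sdDriver <- diff(boneFractionRange) / sqrt(12)
    tm$noiseSd <- abs(tm$slope) * sdDriver * sqrt(1 / r^2 - 1)
    tm[c("target", "intercept", "slope", "noiseSd", "type")]
}

#' Construct a cohort specification
#'
#' @param nCases number of cases; each case contributes one row (and one
#'   phantom image) per region.
#' @param regions character vector of region labels; all regions of a case
#'   share its latent bone fraction but have independent texture.
#' @param targetModel per-target affine map and noise sd; see
#'   [defaultTargetModel()].
#' @param boneFractionRange support of the uniform latent bone-fraction
#'   distribution (default 0.15-0.55, spanning osteoporotic to normal
#'   trabecular areal fractions).
#' @param bmdFloorRate fraction of cases whose BMD targets are forced
#'   below the 0.15 exclusion cutoff (exactly \code{round(rate * nCases)}
#'   cases).
#' @param missingRate fraction of cases with one feature value withheld
#'   (exactly \code{round(rate * nCases)} cases).
#' @param phantom [PhantomParams-class] template; its \code{boneFraction}
#'   and \code{seed} are overridden per row.
#' @param seed integer seed governing all cohort randomness.
#' @return A [CohortSpec-class] object.
#' @examples
#' spec <- cohortSpec(nCases = 20, regions = "L1", seed = 3)
#' coh <- generateCohort(spec)
#' @export
cohortSpec <- function(nCases, regions = defaultRegions(),
                       targetModel = defaultTargetModel(),
                       boneFractionRange = c(0.15, 0.55),
                       bmdFloorRate = 0, missingRate = 0,
                       phantom = phantomParams(), seed = 1L) {
    new("CohortSpec", nCases = as.integer(nCases),
        regions = as.character(regions), targetModel = targetModel,
        boneFractionRange = as.numeric(boneFractionRange),
        bmdFloorRate = as.numeric(bmdFloorRate),
        missingRate = as.numeric(missingRate),
        phantom = phantom, seed = as.integer(seed))
}

setMethod("show", "CohortSpec", function(object) {
    cat(sprintf("CohortSpec: %d cases x %d regions, %d targets, seed %d\n",
                object@nCases, length(object@regions),
                nrow(object@targetModel), object@seed))
    cat(sprintf("  bone fraction ~ U(%.2f, %.2f); floor rate %.3f; missing rate %.3f\n",
                object@boneFractionRange[1], object@boneFractionRange[2],
                object@bmdFloorRate, object@missingRate))
})

#' A cohort of slice images with reference targets
#'
#' One row per (case, region): a 2D HU image (plain numeric matrix) plus
#' the case's reference targets and missing-feature flag. Produced by
#' [generateCohort()] or read from disk by [readCohort()].
#'
#' @slot images list of numeric HU matrices, one per row (may be empty
#'   when the cohort was generated with \code{images = FALSE}).
#' @slot data [S4Vectors::DataFrame-class] with columns \code{caseId},
#'   \code{region}, \code{boneFraction} (NA when unknown), one column per
#'   target, and \code{missingFeature} (NA or a feature index into the
#'   default 45-feature layout).
#' @slot meta list of provenance (e.g. the generating [CohortSpec-class]).
#' @exportClass BoneCohort
setClass("BoneCohort", representation(
    images = "list", data = "DataFrame", meta = "list"))

setValidity("BoneCohort", function(object) {
    msg <- character(0)
    if (length(object@images) &&
        length(object@images) != nrow(object@data))
        msg <- c(msg, "images must be empty or match the number of rows")
    need <- c("caseId", "region", "missingFeature")
    if (!all(need %in% colnames(object@data)))
        msg <- c(msg, paste("data must have columns",
                            paste(need, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

setMethod("show", "BoneCohort", function(object) {
    cat(sprintf("BoneCohort: %d rows (%d cases x regions), %d images, %d targets\n",
                nrow(object@data), length(unique(object@data$caseId)),
                length(object@images), length(targetNames(object))))
})

#' A gray-level co-occurrence matrix
#'
#' Joint frequency of discretized intensity-level pairs at a fixed pixel
#' offset: entry (i, j) is the normalised count of pixel pairs with levels
#' i and j that are \code{distance} apart along \code{orientation}. When
#' \code{symmetric}, each pair contributes to both (i, j) and (j, i).
#'
#' @slot p levels x levels numeric matrix, nonnegative, summing to 1.
#' @slot levels number of intensity levels n (matrix is n x n).
#' @slot orientation "horizontal" or "vertical".
#' @slot distance positive integer pixel offset.
#' @slot symmetric logical, whether both pair orders were accumulated.
#' @seealso [computeGLCM()], [glcmStatistics()]
#' @exportClass GLCM
setClass("GLCM", representation(
    p = "matrix", levels = "integer", orientation = "character",
    distance = "integer", symmetric = "logical"))

setValidity("GLCM", function(object) {
    msg <- character(0)
    p <- object@p
    n <- object@levels
    if (nrow(p) != n || ncol(p) != n)
        msg <- c(msg, "p must be levels x levels")
    if (any(p < 0))
        msg <- c(msg, "GLCM entries must be nonnegative")
    if (abs(sum(p) - 1) > 1e-12)
        msg <- c(msg, "GLCM entries must sum to 1")
    if (isTRUE(object@symmetric) && !isTRUE(all.equal(p, t(p), tolerance = 1e-12)))
        msg <- c(msg, "symmetric GLCM must equal its transpose")
    if (!object@orientation %in% c("horizontal", "vertical"))
        msg <- c(msg, "orientation must be 'horizontal' or 'vertical'")
    if (object@distance < 1L)
        msg <- c(msg, "distance must be >= 1")
    if (length(msg)) msg else TRUE
})

setMethod("show", "GLCM", function(object) {
    cat(sprintf("GLCM: %d levels, %s, distance %d, %s\n", object@levels,
                object@orientation, object@distance,
                if (object@symmetric) "symmetric" else "asymmetric"))
})

#' A rectangular region of interest
#'
#' Axis-aligned rectangle in 0-based, half-open coordinates:
#' rows \code{[row0, row0 + height)}, columns \code{[col0, col0 + width)}.
#'
#' @slot row0,col0 nonnegative integer offsets of the top-left corner.
#' @slot height,width positive integer extents.
#' @seealso [rectROI()], [selectRectangle()], [cropROI()]
#' @exportClass RectROI
setClass("RectROI", representation(
    row0 = "integer", col0 = "integer", height = "integer",
    width = "integer"))

setValidity("RectROI", function(object) {
    msg <- character(0)
    if (object@row0 < 0L || object@col0 < 0L)
        msg <- c(msg, "row0 and col0 must be nonnegative")
    if (object@height < 1L || object@width < 1L)
        msg <- c(msg, "height and width must be positive")
    if (length(msg)) msg else TRUE
})

#' Construct a rectangular ROI
#'
#' @param row0,col0 0-based offsets of the top-left corner.
#' @param height,width positive extents in pixels.
#' @return A [RectROI-class] object.
#' @export
rectROI <- function(row0, col0, height, width) {
    new("RectROI", row0 = as.integer(row0), col0 = as.integer(col0),
        height = as.integer(height), width = as.integer(width))
}

setMethod("show", "RectROI", function(object) {
    cat(sprintf("RectROI: rows [%d, %d), cols [%d, %d)  (%dx%d)\n",
                object@row0, object@row0 + object@height, object@col0,
                object@col0 + object@width, object@height, object@width))
})

#' A fitted linear BMD estimation model
#'
#' Unregularised least-squares model fitted on z-scored features and
#' target. The model stores the normalisation statistics, so
#' \code{predict()} accepts features on the original HU-derived scale and
#' returns predictions in original target units.
#'
#' @slot bias intercept on the normalised scale.
#' @slot weights named weights, one per feature (zero for dropped
#'   features).
#' @slot featureMeans,featureSds per-feature normalisation statistics.
#' @slot targetMean,targetSd target normalisation statistics.
#' @slot targetName label of the modelled target.
#' @slot dropped names of zero-variance features excluded from the fit.
#' @seealso [fitBMDModel()], [evaluateModel()]
#' @exportClass BMDModel
setClass("BMDModel", representation(
    bias = "numeric", weights = "numeric", featureMeans = "numeric",
    featureSds = "numeric", targetMean = "numeric", targetSd = "numeric",
    targetName = "character", dropped = "character"))

setValidity("BMDModel", function(object) {
    msg <- character(0)
    if (length(object@weights) != length(object@featureMeans) ||
        length(object@weights) != length(object@featureSds))
        msg <- c(msg, "weights and normalisation statistics must have equal length")
    if (is.null(names(object@weights)))
        msg <- c(msg, "weights must be named by feature")
    if (!all(is.finite(c(object@bias, object@weights))))
        msg <- c(msg, "model coefficients must be finite")
    if (object@targetSd <= 0)
        msg <- c(msg, "targetSd must be positive")
    if (length(msg)) msg else TRUE
})

setMethod("show", "BMDModel", function(object) {
    cat(sprintf("BMDModel for '%s': %d features (%d dropped), bias %.4g\n",
                object@targetName, length(object@weights),
                length(object@dropped), object@bias))
})

#' Correlation-based feature selection result
#'
#' Per-target Pearson correlations of every feature with the reference
#' value, the top-k features per target (ranked by |r|, ties broken by
#' lower index), and the cross-target occurrence counts.
#'
#' @slot correlations features x targets matrix of Pearson r.
#' @slot top k x targets integer matrix of 1-based feature indices, ranked
#'   by decreasing |r| within each column.
#' @slot counts named integer vector: per feature, the number of targets
#'   whose top-k includes it; sums to k * n_targets.
#' @seealso [selectFeatures()], [maxIndexCounts()]
#' @exportClass SelectionResult
setClass("SelectionResult", representation(
    correlations = "matrix", top = "matrix", counts = "integer"))

setValidity("SelectionResult", function(object) {
    msg <- character(0)
    if (length(object@counts) != nrow(object@correlations))
        msg <- c(msg, "counts must have one entry per feature")
    if (sum(object@counts) != nrow(object@top) * ncol(object@top))
        msg <- c(msg, "counts must sum to k * n_targets")
    if (any(apply(object@top, 2, anyDuplicated) > 0))
        msg <- c(msg, "top indices must be distinct within a target")
    if (length(msg)) msg else TRUE
})

setMethod("show", "SelectionResult", function(object) {
    cat(sprintf("SelectionResult: %d features x %d targets, top-%d per target\n",
                nrow(object@correlations), ncol(object@correlations),
                nrow(object@top)))
    best <- sort(object@counts, decreasing = TRUE)
    best <- best[best > 0]
    cat("  most frequent:",
        paste(sprintf("%s(%d)", names(head(best, 5)), head(best, 5)),
              collapse = ", "), "\n")
})

#' Feature table as a SummarizedExperiment
#'
#' Container for an extracted feature table: the \code{"features"} assay
#' holds the feature matrix (features in rows, samples - i.e. (case,
#' region) pairs - in columns), and \code{colData} carries case id,
#' region, reference targets and the latent bone fraction when known.
#'
#' @seealso [extractFeatures()], [featureMatrix()]
#' @exportClass TextureExperiment
setClass("TextureExperiment", contains = "SummarizedExperiment")

setValidity("TextureExperiment", function(object) {
    msg <- character(0)
    if (!"features" %in% assayNames(object))
        msg <- c(msg, "assay 'features' is required")
    if (!all(c("caseId", "region") %in% colnames(colData(object))))
        msg <- c(msg, "colData must contain caseId and region")
    if (length(msg)) msg else TRUE
})
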