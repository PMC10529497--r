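# Case exclusion, z-score normalisation, linear least-squares estimation
# and evaluation (Pearson correlation + MSE).

#' Apply the case-exclusion rule
#'
#' Removes samples with any missing feature value and, for BMD-type
#' targets, samples whose reference value is strictly below
#' \code{bmdFloor} (default 0.15 g/cm2; a value exactly at the cutoff is
#' retained). BMC targets are on a different scale and use only the
#' missingness rule. An audit log records the reason for each removal.
#'
#' @param te a [TextureExperiment-class].
#' @param target name of the target column in \code{colData(te)}.
#' @param bmdFloor exclusion cutoff for BMD-type targets.
#' @param bmdTarget logical; is this a BMD-type target? Defaults to
#'   matching "bmd" in the target name.
#' @return list with \code{experiment} (the filtered
#'   [TextureExperiment-class]) and \code{log} (data.frame \code{caseId,
#'   region, reason} for the removed rows).
#' @examples
#' coh <- generateCohort(cohortSpec(20, "L1", bmdFloorRate = 0.1, seed = 4))
#' te <- extractFeatures(coh)
#' ex <- excludeCases(te, "total_lumbar_bmd")
#' nrow(ex$log)  # 2 of 20 below the cutoff
#' @export
excludeCases <- function(te, target, bmdFloor = 0.15,
                         bmdTarget = grepl("bmd", target,
                                           ignore.case = TRUE)) {
    stopifnot(is(te, "TextureExperiment"))
    cd <- colData(te)
    if (!target %in% colnames(cd))
        stop("target '", target, "' not found in colData")
    y <- cd[[target]]
    X <- assay(te, "features")
    missing <- apply(X, 2, anyNA) | is.na(y)
    below <- bmdTarget & !is.na(y) & y < bmdFloor
    drop <- missing | below
    reason <- ifelse(missing, "missing feature or target value",
                     sprintf("BMD %.3f below %.2f cutoff", y, bmdFloor))
    log <- data.frame(caseId = cd$caseId[drop], region = cd$region[drop],
                      reason = reason[drop], stringsAsFactors = FALSE)
    if (all(drop))
        stop("empty cohort: all samples excluded for target '", target, "'")
    list(experiment = te[, !drop], log = log)
}

#' z-score features and target
#'
#' Normalises each feature column and the target to sample mean 0 and
#' sample sd 1 (sd with the n-1 denominator). Zero-variance features are
#' dropped with a warning (they carry weight 0 in the fitted model); a
#' zero-variance target is an error.
#'
#' @param X samples x features numeric matrix (no missing values).
#' @param y numeric target vector.
#' @param tol variance tolerance below which a column counts as constant.
#' @return list with \code{X}, \code{y} (normalised), \code{featureMeans},
#'   \code{featureSds} (for all input features, including dropped ones),
#'   \code{targetMean}, \code{targetSd}, \code{dropped} (feature names).
#' @export
normalizeFeatures <- function(X, y, tol = 1e-12) {
    stopifnot(is.matrix(X), nrow(X) == length(y), nrow(X) >= 2,
              !anyNA(X), !anyNA(y))
    mu <- colMeans(X)
    sds <- apply(X, 2, stats::sd)
    dropped <- colnames(X)[sds <= tol]
    if (length(dropped))
        warning("dropping zero-variance feature(s): ",
                paste(dropped, collapse = ", "))
    keep <- sds > tol
    Xn <- sweep(sweep(X[, keep, drop = FALSE], 2, mu[keep]), 2, sds[keep],
                "/")
    ym <- mean(y); ys <- stats::sd(y)
    if (ys <= tol) stop("zero-variance target")
    list(X = Xn, y = (y - ym) / ys, featureMeans = mu, featureSds = sds,
         targetMean = ym, targetSd = ys, dropped = dropped)
}

#' Fit an unregularised linear model on normalised data
#'
#' Least-squares minimiser of \eqn{\sum_j (y_j - w_0 - \sum_i w_i
#' x_{ij})^2} via QR; rank-deficient designs (e.g. duplicated feature
#' columns) fall back to the minimum-norm solution (Moore-Penrose
#' pseudoinverse). No regularisation is applied.
#'
#' @param X samples x features matrix (already normalised).
#' @param y normalised target vector.
#' @return list with \code{bias} and named \code{weights}.
#' @export
fitLinearModel <- function(X, y) {
    stopifnot(is.matrix(X), nrow(X) == length(y), nrow(X) >= 2,
              !anyNA(X), !anyNA(y))
    A <- cbind(`(bias)` = 1, X)
    qrA <- qr(A)
    if (qrA$rank < ncol(A)) {
        w <- as.numeric(MASS::ginv(A) %*% y)
    } else {
        w <- as.numeric(qr.coef(qrA, y))
    }
    names(w) <- colnames(A)
    list(bias = w[[1]], weights = w[-1])
}

#' Fit a BMD estimation model for one target
#'
#' End-to-end fit on a feature table: applies the exclusion rule
#' ([excludeCases()]), z-scores features and target
#' ([normalizeFeatures()]), and solves the unregularised least-squares
#' problem ([fitLinearModel()]). The returned [BMDModel-class] carries the
#' normalisation statistics, so predictions are produced from and
#' reported in original units.
#'
#' @param te a [TextureExperiment-class].
#' @param target target column name in \code{colData(te)}.
#' @param bmdFloor,bmdTarget exclusion-rule parameters; see
#'   [excludeCases()].
#' @return list with \code{model} ([BMDModel-class]), \code{experiment}
#'   (the filtered [TextureExperiment-class] actually fitted) and
#'   \code{exclusionLog}.
#' @examples
#' coh <- generateCohort(cohortSpec(30, "L1", seed = 8))
#' te <- extractFeatures(coh)
#' fit <- fitBMDModel(te, "femur_neck_bmd")
#' fit$model
#' @export
fitBMDModel <- function(te, target, bmdFloor = 0.15,
                        bmdTarget = grepl("bmd", target,
                                          ignore.case = TRUE)) {
    ex <- excludeCases(te, target, bmdFloor, bmdTarget)
    teF <- ex$experiment
    X <- featureMatrix(teF)
    y <- colData(teF)[[target]]
    nm <- normalizeFeatures(X, y)
    fit <- fitLinearModel(nm$X, nm$y)
    weights <- setNames(numeric(ncol(X)), colnames(X))
    weights[names(fit$weights)] <- fit$weights
    model <- new("BMDModel", bias = fit$bias, weights = weights,
                 featureMeans = nm$featureMeans, featureSds = nm$featureSds,
                 targetMean = nm$targetMean, targetSd = nm$targetSd,
                 targetName = target, dropped = nm$dropped)
    list(model = model, experiment = teF, exclusionLog = ex$log)
}

.predictMatrix <- function(object, X) {
    stopifnot(is.matrix(X), ncol(X) == length(object@weights))
    if (!is.null(colnames(X)) &&
        !identical(colnames(X), names(object@weights)))
        X <- X[, names(object@weights), drop = FALSE]
    sds <- object@featureSds
    keep <- !(names(object@weights) %in% object@dropped)
    Xn <- sweep(sweep(X[, keep, drop = FALSE], 2,
                      object@featureMeans[keep]), 2, sds[keep], "/")
    yn <- object@bias + as.numeric(Xn %*% object@weights[keep])
    yn * object@targetSd + object@targetMean
}

#' Predict BMD/BMC from features
#'
#' @param object a [BMDModel-class].
#' @param newdata a [TextureExperiment-class] or a samples x features
#'   matrix in original (unnormalised) units.
#' @param ... ignored.
#' @return Numeric vector of predictions in original target units.
#' @export
setMethod("predict", "BMDModel", function(object, newdata, ...) {
    X <- if (is(newdata, "TextureExperiment")) featureMatrix(newdata)
         else newdata
    .predictMatrix(object, X)
})

#' Evaluate a fitted model
#'
#' Pearson correlation coefficient (CC) between predictions and reference
#' values, and mean squared error (MSE) on the original target scale.
#'
#' @param model a [BMDModel-class].
#' @param newdata a [TextureExperiment-class] or samples x features
#'   matrix.
#' @param y reference target values; defaults to the model's target
#'   column of \code{colData(newdata)} when \code{newdata} is a
#'   [TextureExperiment-class].
#' @return One-row data.frame: \code{target, cc, mse, n}.
#' @export
evaluateModel <- function(model, newdata, y = NULL) {
    stopifnot(is(model, "BMDModel"))
    if (is.null(y)) {
        if (!is(newdata, "TextureExperiment"))
            stop("y must be supplied when newdata is a matrix")
        y <- colData(newdata)[[model@targetName]]
    }
    pred <- predict(model, newdata)
    if (length(y) < 3)
        stop("correlation coefficient undefined for fewer than 3 cases")
    data.frame(target = model@targetName,
               cc = stats::cor(pred, y),
               mse = mean((pred - y)^2),
               n = length(y), stringsAsFactors = FALSE)
}

#' Serialise / read a fitted model as JSON
#'
#' The JSON object stores the bias, per-feature weights, normalisation
#' statistics, target name and dropped features - everything needed to
#' reproduce predictions.
#'
#' @param model a [BMDModel-class].
#' @param path JSON file path.
#' @return \code{writeBMDModel}: the path, invisibly; \code{readBMDModel}:
#'   a [BMDModel-class].
#' @export
writeBMDModel <- function(model, path) {
    stopifnot(is(model, "BMDModel"))
    obj <- list(target = model@targetName, bias = model@bias,
                weights = as.list(model@weights),
                feature_means = as.list(model@featureMeans),
                feature_sds = as.list(model@featureSds),
                target_mean = model@targetMean,
                target_sd = model@targetSd,
                dropped = as.list(model@dropped))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}

#' @rdname writeBMDModel
#' @export
readBMDModel <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    new("BMDModel", bias = obj$bias, weights = unlist(obj$weights),
        featureMeans = unlist(obj$feature_means),
        featureSds = unlist(obj$feature_sds),
        targetMean = obj$target_mean, targetSd = obj$target_sd,
        targetName = obj$target,
        dropped = as.character(unlist(obj$dropped)))
}
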