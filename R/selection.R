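# Correlation-based feature ranking: per-target Pearson r, top-k
# extraction, and cross-target occurrence counting.

#' Per-feature Pearson correlation with a target
#'
#' Standard Pearson correlation of each feature column with the reference
#' value. Zero-variance features get r = 0 with a warning (no linear
#' association is measurable); a zero-variance target is an error.
#'
#' @param X samples x features matrix, missing-value rows already
#'   excluded.
#' @param y numeric target (length >= 3).
#' @return Named numeric vector of correlations, one per feature.
#' @export
featureTargetCorrelations <- function(X, y) {
    stopifnot(is.matrix(X), nrow(X) == length(y), !anyNA(X), !anyNA(y))
    if (length(y) < 3)
        stop("at least 3 cases are required for correlation")
    if (stats::sd(y) == 0) stop("zero-variance target")
    sds <- apply(X, 2, stats::sd)
    r <- rep(0, ncol(X))
    if (any(sds == 0))
        warning("zero-variance feature(s) assigned r = 0: ",
                paste(colnames(X)[sds == 0], collapse = ", "))
    ok <- sds > 0
    r[ok] <- as.numeric(stats::cor(X[, ok, drop = FALSE], y))
    setNames(r, colnames(X))
}

#' Top-k features by correlation strength
#'
#' Indices of the k features with the largest |r| ("strongest
#' correlation" read as magnitude: strongly negative texture-density
#' correlations are equally informative), sorted by decreasing |r|, ties
#' broken by lower feature index so reruns are bit-stable. A signed mode
#' ranks by r itself.
#'
#' @param r numeric vector of finite correlations.
#' @param k how many features to return (default 5).
#' @param absolute rank by |r| (default) or by signed r.
#' @return Integer vector of k 1-based feature indices.
#' @examples
#' topFeatures(c(0.2, -0.9, 0.5, 0.1, 0.8, 0.3))
#' @export
topFeatures <- function(r, k = 5L, absolute = TRUE) {
    stopifnot(all(is.finite(r)), k >= 1, k <= length(r))
    key <- if (absolute) abs(r) else r
    ord <- order(-key, seq_along(r))
    ord[seq_len(k)]
}

#' Cross-target top-k occurrence counts
#'
#' Counts, for every feature, in how many targets' top-k sets it appears.
#' The counts always sum to k x n_targets.
#'
#' @param topList list of integer index vectors (one per target).
#' @param nFeatures total number of features.
#' @return Named integer vector of length \code{nFeatures}.
#' @export
maxIndexCounts <- function(topList, nFeatures = 45L) {
    stopifnot(length(topList) >= 1)
    idx <- unlist(topList, use.names = FALSE)
    stopifnot(all(idx >= 1), all(idx <= nFeatures))
    counts <- tabulate(idx, nbins = nFeatures)
    setNames(as.integer(counts), paste0("f", seq_len(nFeatures)))
}

#' Correlation-based feature selection across targets
#'
#' For each target: applies the exclusion rule, computes per-feature
#' Pearson correlations with the reference value, and extracts the top-k
#' features; then counts top-k membership across targets. This identifies
#' the texture features with the most consistent influence on the
#' BMD/BMC estimates.
#'
#' @param te a [TextureExperiment-class].
#' @param targets character vector of target column names (default: all
#'   known targets of \code{te}).
#' @param k top-k size (default 5).
#' @param absolute rank by |r|; see [topFeatures()].
#' @param bmdFloor exclusion cutoff; see [excludeCases()].
#' @return A [SelectionResult-class].
#' @examples
#' coh <- generateCohort(cohortSpec(30, "L1", seed = 21))
#' te <- extractFeatures(coh)
#' sel <- selectFeatures(te)
#' sum(selectionCounts(sel))  # 5 x 8
#' @export
selectFeatures <- function(te, targets = targetNames(te), k = 5L,
                           absolute = TRUE, bmdFloor = 0.15) {
    stopifnot(is(te, "TextureExperiment"), length(targets) >= 1)
    fn <- rownames(assay(te, "features"))
    corr <- matrix(NA_real_, length(fn), length(targets),
                   dimnames = list(fn, targets))
    top <- matrix(NA_integer_, k, length(targets),
                  dimnames = list(NULL, targets))
    for (t in targets) {
        ex <- excludeCases(te, t, bmdFloor = bmdFloor)
        X <- featureMatrix(ex$experiment)
        y <- colData(ex$experiment)[[t]]
        r <- featureTargetCorrelations(X, y)
        corr[, t] <- r
        top[, t] <- topFeatures(r, k = k, absolute = absolute)
    }
    counts <- maxIndexCounts(asplit(top, 2), nFeatures = length(fn))
    names(counts) <- fn
    new("SelectionResult", correlations = corr, top = top,
        counts = counts)
}

#' Write selection results as CSV
#'
#' Writes the per-target correlation table
#' (\code{<prefix>_correlations.csv}: feature index, feature name, one
#' column of Pearson r per target) and the cross-target count table
#' (\code{<prefix>_counts.csv}: feature index, feature name, count - the
#' bar-chart table of top-5 membership across targets).
#'
#' @param sel a [SelectionResult-class].
#' @param prefix output path prefix.
#' @return Character vector of the two paths, invisibly.
#' @export
writeSelection <- function(sel, prefix) {
    stopifnot(is(sel, "SelectionResult"))
    fn <- rownames(sel@correlations)
    corrPath <- paste0(prefix, "_correlations.csv")
    corrDf <- data.frame(feature_index = seq_along(fn), feature = fn,
                         stringsAsFactors = FALSE)
    corrDf <- cbind(corrDf, as.data.frame(sel@correlations,
                                          row.names = FALSE))
    utils::write.csv(corrDf, corrPath, row.names = FALSE)
    countPath <- paste0(prefix, "_counts.csv")
    utils::write.csv(data.frame(feature_index = seq_along(fn),
                                feature = fn,
                                count = as.integer(sel@counts)),
                     countPath, row.names = FALSE)
    invisible(c(correlations = corrPath, counts = countPath))
}
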