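# Per-ROI feature vectors (histogram + GLCM) and cohort-level extraction.

.DEFAULT_LEVELS <- c(16L, 32L, 64L, 128L)
.DEFAULT_ORIENTATIONS <- c("horizontal", "vertical")
.DEFAULT_STATISTICS <- c("entropy", "contrast", "correlation",
                         "homogeneity", "variance")

#' Histogram (intensity) features of an ROI
#'
#' Population moments of the pixel intensities: mean, sd (divide by N),
#' skewness \eqn{m_3 / sd^3}, excess kurtosis \eqn{m_4 / sd^4 - 3}, and
#' Shannon entropy (bits) of a 256-bin equal-width histogram over the
#' ROI's range. A constant ROI returns \code{(c, 0, 0, 0, 0)}: skewness,
#' kurtosis and entropy take the 0 convention when sd = 0 so feature
#' vectors stay finite.
#'
#' @param x numeric matrix (nonempty).
#' @param nbins number of histogram bins for the entropy (default 256).
#' @return Named numeric(5): \code{mean, sd, skewness, kurtosis, entropy}.
#' @examples
#' histogramFeatures(matrix(c(0, 0, 100, 100), 2))
#' @export
histogramFeatures <- function(x, nbins = 256L) {
    stopifnot(length(x) > 0)
    v <- as.numeric(x)
    n <- length(v)
    mu <- mean(v)
    m2 <- sum((v - mu)^2) / n
    s <- sqrt(m2)
    if (s == 0) {
        skew <- 0; kurt <- 0; ent <- 0
    } else {
        skew <- (sum((v - mu)^3) / n) / s^3
        kurt <- (sum((v - mu)^4) / n) / s^4 - 3
        rng <- range(v)
        bin <- floor((v - rng[1]) / (rng[2] - rng[1]) * nbins) + 1L
        bin[bin > nbins] <- nbins
        q <- tabulate(bin, nbins) / n
        q <- q[q > 0]
        ent <- -sum(q * log2(q))
    }
    c(mean = mu, sd = s, skewness = skew, kurtosis = kurt, entropy = ent)
}

#' Names of the extracted features, in canonical order
#'
#' Five histogram features (\code{hist_*}) followed by the GLCM features
#' \code{glcm_<stat>_<levels>_<h|v>}, ordered statistic-major, then by
#' level count, then orientation. The defaults give the canonical
#' 45-feature layout (5 + 5 statistics x 4 level counts x 2 orientations).
#'
#' @param levels GLCM level counts.
#' @param orientations GLCM orientations ("horizontal"/"vertical").
#' @param statistics GLCM statistic names.
#' @return Character vector of feature names.
#' @examples
#' length(featureNames())  # 45
#' @export
featureNames <- function(levels = .DEFAULT_LEVELS,
                         orientations = .DEFAULT_ORIENTATIONS,
                         statistics = .DEFAULT_STATISTICS) {
    hist <- paste0("hist_", c("mean", "sd", "skewness", "kurtosis",
                              "entropy"))
    grid <- expand.grid(orientation = substr(orientations, 1, 1),
                        levels = levels, stat = statistics,
                        stringsAsFactors = FALSE)
    c(hist, sprintf("glcm_%s_%d_%s", grid$stat, grid$levels,
                    grid$orientation))
}

#' Extract the feature vector of one ROI
#'
#' Computes the 5 histogram features and, for every (level count,
#' orientation) pair, one GLCM with the requested statistics - with the
#' defaults, 8 GLCMs (levels 16/32/64/128 x horizontal/vertical) and 5
#' statistics each, i.e. the canonical 45-feature vector in
#' [featureNames()] order.
#'
#' @param roi numeric HU matrix, at least 8x8.
#' @param levels,orientations,statistics GLCM configuration; see
#'   [featureNames()].
#' @param distance GLCM pixel offset.
#' @param symmetric symmetric GLCM accumulation.
#' @return Named numeric vector (length 45 with the defaults).
#' @examples
#' img <- generatePhantom(phantomParams(seed = 5))
#' fv <- extractFeatureVector(img)
#' length(fv)  # 45
#' @export
extractFeatureVector <- function(roi, levels = .DEFAULT_LEVELS,
                                 orientations = .DEFAULT_ORIENTATIONS,
                                 statistics = .DEFAULT_STATISTICS,
                                 distance = 1L, symmetric = TRUE) {
    stopifnot(is.matrix(roi))
    if (nrow(roi) < 8L || ncol(roi) < 8L)
        stop("ROI must be at least 8x8")
    hf <- histogramFeatures(roi)
    nl <- length(levels); no <- length(orientations)
    statMat <- matrix(NA_real_, length(statistics), nl * no)
    col <- 0L
    for (n in levels) {
        disc <- discretize(roi, n)
        for (o in orientations) {
            col <- col + 1L
            p <- .glcmP(disc, n, o, distance, symmetric)
            statMat[, col] <- .glcmStatsCore(p, n, statistics)
        }
    }
    # statMat columns are (levels x orientation) pairs in loop order;
    # flatten statistic-major to match featureNames()
    out <- c(hf, as.numeric(t(statMat)))
    names(out) <- featureNames(levels, orientations, statistics)
    out
}

#' Extract features for a whole cohort
#'
#' Applies [extractFeatureVector()] to every (case, region) row of a
#' cohort and assembles a [TextureExperiment-class]. Per-row ROIs come
#' from \code{rois} when given (a data.frame with \code{row0, col0,
#' height, width}, one row per cohort row, 0-based half-open), from the
#' cohort's own manifest ROI columns when present, and default to the
#' full image. Rows flagged with a \code{missingFeature} index get that
#' feature set to \code{NA}, emulating a case with an unavailable
#' measurement.
#'
#' @param cohort a [BoneCohort-class] with images.
#' @param rois optional per-row ROI data.frame.
#' @param levels,orientations,statistics,distance,symmetric passed to
#'   [extractFeatureVector()].
#' @return A [TextureExperiment-class]: assay \code{"features"} is
#'   features x samples; \code{colData} carries the cohort annotations.
#' @examples
#' coh <- generateCohort(cohortSpec(nCases = 4, regions = "L1", seed = 9))
#' te <- extractFeatures(coh)
#' dim(featureMatrix(te))  # 4 x 45
#' @export
extractFeatures <- function(cohort, rois = NULL,
                            levels = .DEFAULT_LEVELS,
                            orientations = .DEFAULT_ORIENTATIONS,
                            statistics = .DEFAULT_STATISTICS,
                            distance = 1L, symmetric = TRUE) {
    stopifnot(is(cohort, "BoneCohort"))
    if (!length(cohort@images))
        stop("cohort has no images; regenerate with images = TRUE")
    df <- cohort@data
    nRows <- nrow(df)
    if (is.null(rois) && all(c("row0", "col0", "height", "width") %in%
                             colnames(df)))
        rois <- as.data.frame(df[c("row0", "col0", "height", "width")])
    fn <- featureNames(levels, orientations, statistics)
    fmat <- matrix(NA_real_, length(fn), nRows,
                   dimnames = list(fn, NULL))
    for (i in seq_len(nRows)) {
        img <- cohort@images[[i]]
        if (!is.null(rois)) {
            r <- rectROI(rois$row0[i], rois$col0[i], rois$height[i],
                         rois$width[i])
            img <- cropROI(img, r)
        }
        fmat[, i] <- extractFeatureVector(img, levels, orientations,
                                          statistics, distance, symmetric)
    }
    miss <- df$missingFeature
    for (i in which(!is.na(miss)))
        if (miss[i] <= nrow(fmat)) fmat[miss[i], i] <- NA_real_
    keep <- setdiff(colnames(df), c("row0", "col0", "height", "width"))
    se <- SummarizedExperiment(assays = list(features = fmat),
                               colData = df[keep])
    te <- new("TextureExperiment", se)
    metadata(te)$targetNames <- targetNames(cohort)
    metadata(te)$extraction <- list(levels = levels,
                                    orientations = orientations,
                                    statistics = statistics,
                                    distance = distance,
                                    symmetric = symmetric)
    te
}

#' Write a feature table as CSV
#'
#' One row per (case, region); columns \code{case_id, region} followed by
#' the named features in canonical order.
#'
#' @param te a [TextureExperiment-class].
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
writeFeatureTable <- function(te, path) {
    stopifnot(is(te, "TextureExperiment"))
    cd <- colData(te)
    out <- data.frame(case_id = cd$caseId, region = cd$region,
                      stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(featureMatrix(te)))
    utils::write.csv(out, path, row.names = FALSE)
    invisible(path)
}
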