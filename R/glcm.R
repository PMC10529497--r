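# Gray-level co-occurrence matrices and their scalar statistics.

#' Discretize an ROI to integer intensity levels
#'
#' Equal-width binning of the ROI's own range onto levels \code{1..n}
#' (per-ROI min-max normalisation): bin edges split
#' \code{[min(x), max(x)]} into \code{levels} equal parts, the maximum
#' maps to level \code{n}, and a constant ROI maps everywhere to level 1.
#'
#' @param x numeric matrix (nonempty).
#' @param levels integer number of levels, >= 2.
#' @return Integer matrix with values in \code{1..levels}.
#' @examples
#' discretize(matrix(c(0, 200, 100, 300), 2), 4)
#' @export
discretize <- function(x, levels) {
    stopifnot(is.matrix(x), length(x) > 0, levels >= 2)
    levels <- as.integer(levels)
    rng <- range(x)
    if (rng[1] == rng[2])
        return(matrix(1L, nrow(x), ncol(x)))
    idx <- floor((x - rng[1]) / (rng[2] - rng[1]) * levels) + 1L
    idx[idx > levels] <- levels          # the maximum maps to level n
    matrix(as.integer(idx), nrow(x), ncol(x))
}

#' Compute a gray-level co-occurrence matrix
#'
#' Counts pairs of pixels \code{distance} apart along the given
#' orientation (offset (0, d) for horizontal, (d, 0) for vertical) in a
#' level image, optionally accumulating both pair orders (symmetric), and
#' normalises by the total count.
#'
#' @param disc integer matrix with values in \code{1..levels} (from
#'   [discretize()]).
#' @param levels number of intensity levels.
#' @param orientation "horizontal" or "vertical".
#' @param distance positive integer pixel offset (default 1, adjacent
#'   pixels).
#' @param symmetric accumulate both (i, j) and (j, i) per pair (default
#'   TRUE, treating pairs as unordered).
#' @return A [GLCM-class].
#' @examples
#' g <- computeGLCM(matrix(c(1L, 1L, 1L, 2L), 2), levels = 2)
#' glcmMatrix(g)
#' @export
computeGLCM <- function(disc, levels,
                        orientation = c("horizontal", "vertical"),
                        distance = 1L, symmetric = TRUE) {
    orientation <- match.arg(orientation)
    stopifnot(is.matrix(disc), levels >= 2, distance >= 1)
    levels <- as.integer(levels); distance <- as.integer(distance)
    if (min(disc) < 1L || max(disc) > levels)
        stop("level image values must lie in 1..levels")
    p <- .glcmP(disc, levels, orientation, distance, symmetric)
    new("GLCM", p = p, levels = levels, orientation = orientation,
        distance = distance, symmetric = isTRUE(symmetric))
}

# normalised co-occurrence matrix without the S4 wrapper; shared by
# computeGLCM() and the per-cohort extraction hot loop
.glcmP <- function(disc, levels, orientation, distance, symmetric) {
    nr <- nrow(disc); nc <- ncol(disc)
    if (orientation == "horizontal") {
        if (nc <= distance)
            stop("no pixel pairs: image too narrow for horizontal offset ",
                 distance)
        a <- disc[, seq_len(nc - distance), drop = FALSE]
        b <- disc[, distance + seq_len(nc - distance), drop = FALSE]
    } else {
        if (nr <= distance)
            stop("no pixel pairs: image too short for vertical offset ",
                 distance)
        a <- disc[seq_len(nr - distance), , drop = FALSE]
        b <- disc[distance + seq_len(nr - distance), , drop = FALSE]
    }
    counts <- tabulate((b - 1L) * levels + a, nbins = levels * levels)
    p <- matrix(counts, levels, levels)   # [i, j] = count of (a=i, b=j)
    if (symmetric) p <- p + t(p)
    p / sum(p)
}

# cache of per-size index constants used by the statistics
.glcmCache <- new.env(parent = emptyenv())
.glcmConsts <- function(n) {
    key <- as.character(n)
    v <- .glcmCache[[key]]
    if (is.null(v)) {
        i <- matrix(seq_len(n), n, n)        # row level index
        j <- t(i)
        v <- list(i = i, j = j, sqdiff = (i - j)^2,
                  invdiff = 1 / (1 + abs(i - j)), ij = i * j)
        .glcmCache[[key]] <- v
    }
    v
}

#' Scalar statistics of a GLCM
#'
#' Computes the requested Haralick-type statistics of a normalised GLCM
#' \eqn{p}, with level indices \eqn{i, j = 1..n} and marginal means/sds
#' \eqn{\mu_r, \mu_c, \sigma_r, \sigma_c}:
#' \describe{
#'   \item{entropy}{\eqn{-\sum p \log_2 p} (bits; \eqn{0 \log 0 := 0})}
#'   \item{contrast}{\eqn{\sum (i-j)^2 p}}
#'   \item{correlation}{\eqn{\sum (i-\mu_r)(j-\mu_c) p / (\sigma_r \sigma_c)},
#'     defined as 0 when \eqn{\sigma_r \sigma_c = 0}}
#'   \item{homogeneity}{\eqn{\sum p / (1 + |i-j|)}}
#'   \item{variance}{\eqn{\sum (i-\mu_r)^2 p}}
#'   \item{autocorrelation}{\eqn{\sum i \, j \, p} (optional, off the
#'     default feature layout)}
#' }
#'
#' @param glcm a [GLCM-class].
#' @param statistics character vector of statistic names (any of the
#'   above, in the order they should be returned).
#' @return Named numeric vector.
#' @examples
#' g <- computeGLCM(matrix(c(1L, 1L, 1L, 2L), 2), levels = 2)
#' glcmStatistics(g)
#' @export
glcmStatistics <- function(glcm,
                           statistics = c("entropy", "contrast",
                                          "correlation", "homogeneity",
                                          "variance")) {
    stopifnot(is(glcm, "GLCM"))
    known <- c("entropy", "contrast", "correlation", "homogeneity",
               "variance", "autocorrelation")
    bad <- setdiff(statistics, known)
    if (length(bad))
        stop("unknown GLCM statistic(s): ", paste(bad, collapse = ", "))
    .glcmStatsCore(glcm@p, glcm@levels, statistics)
}

.glcmStatsCore <- function(p, n, statistics) {
    k <- .glcmConsts(n)
    lev <- seq_len(n)
    pr <- rowSums(p); pc <- colSums(p)
    mur <- sum(lev * pr); muc <- sum(lev * pc)
    varr <- sum((lev - mur)^2 * pr); varc <- sum((lev - muc)^2 * pc)
    out <- numeric(length(statistics))
    for (s in seq_along(statistics)) {
        out[s] <- switch(statistics[s],
            entropy = { pos <- p[p > 0]; -sum(pos * log2(pos)) },
            contrast = sum(k$sqdiff * p),
            correlation = {
                denom <- sqrt(varr) * sqrt(varc)
                if (denom == 0) 0
                else sum((k$i - mur) * (k$j - muc) * p) / denom
            },
            homogeneity = sum(k$invdiff * p),
            variance = varr,
            autocorrelation = sum(k$ij * p))
    }
    setNames(out, statistics)
}
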