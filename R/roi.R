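# ROI isolation: HU-band thresholding, largest 4-connected component, and
# maximal inscribed rectangle.

#' Threshold the trabecular region of a slice
#'
#' Marks pixels whose attenuation lies in \code{[lowHU, highHU]} (the
#' cancellous-bone band; default 100-500 HU) and keeps the largest
#' 4-connected component, which isolates the contiguous trabecular area
#' from scattered in-band pixels elsewhere in the slice.
#'
#' @param image numeric HU matrix (at least 8x8, finite values).
#' @param lowHU,highHU inclusive HU band, \code{lowHU < highHU}.
#' @return Logical matrix: \code{TRUE} on the retained component.
#' @examples
#' img <- generatePhantom(phantomParams(blurSigma = 2, seed = 1))
#' mask <- thresholdTrabecular(img, 80, 600)
#' @export
thresholdTrabecular <- function(image, lowHU = 100, highHU = 500) {
    stopifnot(is.matrix(image), all(is.finite(image)), lowHU < highHU)
    inBand <- image >= lowHU & image <= highHU
    if (!any(inBand))
        stop("no trabecular region: no pixel in the HU band [",
             lowHU, ", ", highHU, "]")
    lab <- EBImage::bwlabel(inBand)          # 4-connected labelling
    sizes <- tabulate(lab[lab > 0])
    keep <- which.max(sizes)                 # ties: lowest label (raster order)
    matrix(lab == keep, nrow(image), ncol(image))
}

#' Select the maximal inscribed rectangle of a mask
#'
#' Returns the largest-area axis-aligned rectangle fully contained in the
#' mask, restricted to rectangles of at least \code{minHeight} x
#' \code{minWidth} (default 8x8, the smallest ROI that yields stable GLCM
#' statistics). Ties are broken deterministically by smallest \code{row0},
#' then smallest \code{col0}. With \code{minHeight = minWidth = 1} this is
#' the unconstrained maximum-area rectangle.
#'
#' Uses the row-histogram scan (largest rectangle under a histogram per
#' row), O(rows x cols).
#'
#' @param mask logical matrix.
#' @param minHeight,minWidth minimum admissible rectangle sides.
#' @return A [RectROI-class] (0-based, half-open coordinates).
#' @examples
#' m <- matrix(TRUE, 32, 32)
#' selectRectangle(m)  # the full grid
#' @export
selectRectangle <- function(mask, minHeight = 8L, minWidth = 8L) {
    stopifnot(is.matrix(mask), is.logical(mask))
    if (!any(mask)) stop("empty mask")
    nr <- nrow(mask); nc <- ncol(mask)
    heights <- integer(nc)
    best <- NULL; bestArea <- 0L
    consider <- function(row0, col0, h, w) {
        if (h < minHeight || w < minWidth) return()
        area <- h * w
        if (area > bestArea ||
            (area == bestArea && !is.null(best) &&
             (row0 < best[1] || (row0 == best[1] && col0 < best[2])))) {
            best <<- c(row0, col0, h, w); bestArea <<- area
        }
    }
    for (r in seq_len(nr)) {
        heights <- ifelse(mask[r, ], heights + 1L, 0L)
        # largest rectangles under the histogram 'heights', bottom row r
        stack <- integer(0)          # column indices with increasing heights
        for (cidx in seq_len(nc + 1L)) {
            h <- if (cidx <= nc) heights[cidx] else 0L
            start <- cidx
            while (length(stack) && heights[stack[length(stack)]] >= h) {
                top <- stack[length(stack)]
                stack <- stack[-length(stack)]
                hh <- heights[top]
                left <- if (length(stack)) stack[length(stack)] + 1L else 1L
                ww <- cidx - left
                consider(r - hh, left - 1L, hh, ww)
                start <- left
            }
            if (cidx <= nc) stack <- c(stack, cidx)
        }
    }
    if (is.null(best))
        stop("mask admits no rectangle of at least ", minHeight, "x",
             minWidth, " (too small for stable GLCM statistics)")
    rectROI(best[1], best[2], best[3], best[4])
}

#' Crop an image to a rectangular ROI
#'
#' @param image numeric matrix.
#' @param roi a [RectROI-class].
#' @return The sub-matrix covered by \code{roi}.
#' @export
cropROI <- function(image, roi) {
    stopifnot(is(roi, "RectROI"))
    if (roi@row0 + roi@height > nrow(image) ||
        roi@col0 + roi@width > ncol(image))
        stop("ROI extends outside the image")
    image[roi@row0 + seq_len(roi@height), roi@col0 + seq_len(roi@width),
          drop = FALSE]
}

#' Read/write ROI definitions as CSV
#'
#' ROI tables round-trip via CSV with columns \code{case_id, region,
#' row0, col0, height, width} (0-based, half-open).
#'
#' @param rois data.frame with the columns above.
#' @param path CSV file path.
#' @return \code{writeROITable}: the path, invisibly;
#'   \code{readROITable}: the data.frame.
#' @export
writeROITable <- function(rois, path) {
    need <- c("case_id", "region", "row0", "col0", "height", "width")
    stopifnot(all(need %in% names(rois)))
    utils::write.csv(rois[need], path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeROITable
#' @export
readROITable <- function(path) {
    rois <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("case_id", "region", "row0", "col0", "height", "width")
    if (!all(need %in% names(rois)))
        stop("ROI table must have columns ", paste(need, collapse = ", "))
    for (cc in c("row0", "col0", "height", "width"))
        rois[[cc]] <- as.integer(rois[[cc]])
    rois
}
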