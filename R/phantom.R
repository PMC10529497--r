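# Synthetic trabecular phantom: thresholded Gaussian random field with
# two-class HU assignment and optional partial-volume blur.

# Periodic Gaussian kernel, returned in the Fourier domain. Circular
# boundary conditions keep the field stationary and the convolution exact.
.gaussianKernelFFT <- function(nr, nc, sigma) {
    dr <- 0:(nr - 1); dr <- pmin(dr, nr - dr)
    dc <- 0:(nc - 1); dc <- pmin(dc, nc - dc)
    k <- exp(-outer(dr^2, dc^2, "+") / (2 * sigma^2))
    stats::fft(k / sum(k))
}

.circularBlur <- function(x, sigma) {
    if (sigma <= 0) return(x)
    K <- .gaussianKernelFFT(nrow(x), ncol(x), sigma)
    Re(stats::fft(stats::fft(x) * K, inverse = TRUE)) / length(x)
}

#' Generate a trabecular-bone phantom image
#'
#' Simulates the trabecular region of one axial CT cut: a smooth Gaussian
#' random field (correlation length \code{params@correlationLength}) is
#' thresholded at its \code{boneFraction} upper quantile, giving a
#' connected strut-like mask whose areal fraction matches
#' \code{boneFraction} to within one pixel in \code{round()}; strut pixels
#' receive \code{N(boneHUMean, boneHUSd)} HU and marrow pixels
#' \code{N(marrowHUMean, marrowHUSd)}, and the image is optionally blurred
#' (\code{blurSigma}) to emulate partial-volume averaging.
#'
#' Identical parameters (including \code{seed}) give bit-identical images;
#' the caller's RNG state is left untouched.
#'
#' @param params a [PhantomParams-class] object.
#' @return Numeric HU matrix of dimension \code{params@gridSize}, with
#'   attribute \code{"boneFraction"} holding the realised pre-blur strut
#'   fraction.
#' @examples
#' img <- generatePhantom(phantomParams(boneFraction = 0.3, seed = 11))
#' mean(img)  # mean ROI attenuation rises with bone fraction
#' @export
generatePhantom <- function(params) {
    stopifnot(is(params, "PhantomParams"))
    validObject(params)
    withr::with_seed(params@seed, .phantomImpl(params))
}

.phantomImpl <- function(params) {
    nr <- params@gridSize[1]; nc <- params@gridSize[2]
    npix <- nr * nc
    field <- .circularBlur(matrix(stats::rnorm(npix), nr, nc),
                           params@correlationLength)
    k <- min(max(round(params@boneFraction * npix), 1L), npix)
    thr <- sort(field, decreasing = TRUE)[k]
    bone <- field >= thr
    hu <- matrix(0, nr, nc)
    hu[bone] <- stats::rnorm(sum(bone), params@boneHUMean, params@boneHUSd)
    hu[!bone] <- stats::rnorm(npix - sum(bone), params@marrowHUMean,
                              params@marrowHUSd)
    hu <- .circularBlur(hu, params@blurSigma)
    attr(hu, "boneFraction") <- mean(bone)
    hu
}
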