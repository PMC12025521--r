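#' @include AllClasses.R
NULL

#' Convert an image to a single grayscale channel
#'
#' Colour images are collapsed with the standard luma weights
#' `0.299 R + 0.587 G + 0.114 B`; single-channel input passes through
#' unchanged. Intensities keep their input scale.
#'
#' @param x numeric matrix (grayscale) or H x W x 3 array (RGB).
#' @return A numeric matrix.
#' @examples
#' rgb <- array(0, c(4, 4, 3)); rgb[, , 1] <- 1
#' toGrayscale(rgb)[1, 1]  # 0.299
#' @export
toGrayscale <- function(x) {
  if (is.matrix(x)) return(x)
  d <- dim(x)
  if (length(d) == 3L && d[3] == 1L) return(x[, , 1L])
  if (length(d) == 3L && d[3] == 3L)
    return(0.299 * x[, , 1L] + 0.587 * x[, , 2L] + 0.114 * x[, , 3L])
  stop("expected a 1- or 3-channel image, got ",
       if (length(d) == 3L) paste0(d[3], " channels") else "a non-image object")
}

#' Parameters of the center-out ROI scan
#'
#' @param intensityThreshold intensity (0-255 scale) a pixel must exceed to
#'   count as image content. Default 10: the near-black frame around the
#'   echo field is what the scan must skip.
#' @param verticalBand fraction of the image height (top, bottom) restricted
#'   to during the horizontal scan, keeping on-screen annotations near the
#'   top/bottom edges out of the column statistic. Default `c(0.25, 0.75)`.
#' @param minRoiPx minimum acceptable ROI area in pixels; smaller results
#'   signal a failed capture.
#' @return A list of class `roiParams`.
#' @export
roiParams <- function(intensityThreshold = 10, verticalBand = c(0.25, 0.75),
                      minRoiPx = 256L) {
  stopifnot(intensityThreshold >= 0, intensityThreshold <= 255,
            length(verticalBand) == 2L,
            verticalBand[1] >= 0, verticalBand[2] <= 1,
            verticalBand[1] < verticalBand[2], minRoiPx >= 1)
  structure(list(intensityThreshold = intensityThreshold,
                 verticalBand = verticalBand,
                 minRoiPx = as.integer(minRoiPx)),
            class = "roiParams")
}

# walk outward from `start` over a logical supra-threshold profile; returns
# the last TRUE index of the run reached in direction `step` (seeking the
# first TRUE if the start itself is FALSE)
.walkOut <- function(supra, start, step) {
  i <- start
  n <- length(supra)
  while (i >= 1L && i <= n && !supra[i]) i <- i + step
  if (i < 1L || i > n) return(NA_integer_)
  while (i + step >= 1L && i + step <= n && supra[i + step]) i <- i + step
  i
}

#' Locate the region of interest by center-out threshold scanning
#'
#' Finds the informative sub-rectangle of a scan (the echo field, excluding
#' the black frame). Horizontal pass: starting from the middle column and
#' restricted to the vertical band of `params`, walk left and right to the
#' outermost columns whose band maximum still exceeds the threshold.
#' Vertical pass: restricted to those columns, walk up and down from the
#' middle row to the outermost supra-threshold rows. The scans run on the
#' raw (unfiltered) intensities; noise filtering comes after ROI detection
#' so that smoothing cannot blur the very transitions the scan keys on.
#'
#' @param image an [UltrasoundScan-class] or a numeric matrix (0-255 scale).
#' @param params a [roiParams()] list.
#' @return A [ROIBox-class] (0-based, half-open).
#' @examples
#' m <- matrix(0, 100, 100); m[21:60, 31:70] <- 200
#' computeROI(m, roiParams(intensityThreshold = 50, verticalBand = c(0.2, 0.8)))
#' @export
computeROI <- function(image, params = roiParams()) {
  px <- if (is(image, "UltrasoundScan")) pixels(image) else image
  stopifnot(is.matrix(px))
  h <- nrow(px); w <- ncol(px)
  thr <- params$intensityThreshold
  bandRows <- max(1L, floor(params$verticalBand[1] * h) + 1L):
              min(h, ceiling(params$verticalBand[2] * h))

  colSupra <- apply(px[bandRows, , drop = FALSE], 2L, max) > thr
  midCol <- (w + 1L) %/% 2L
  left1 <- .walkOut(colSupra, midCol, -1L)
  right1 <- .walkOut(colSupra, midCol, +1L)
  if (is.na(left1) || is.na(right1))
    stop("empty ROI: no pixel above threshold ", thr,
         " found in the horizontal scan")

  rowSupra <- apply(px[, left1:right1, drop = FALSE], 1L, max) > thr
  midRow <- (h + 1L) %/% 2L
  top1 <- .walkOut(rowSupra, midRow, -1L)
  bottom1 <- .walkOut(rowSupra, midRow, +1L)
  if (is.na(top1) || is.na(bottom1))
    stop("empty ROI: no pixel above threshold ", thr,
         " found in the vertical scan")

  box <- ROIBox(left = left1 - 1L, right = right1, top = top1 - 1L,
                bottom = bottom1)
  if (roiWidth(box) * roiHeight(box) < params$minRoiPx)
    stop("ROI smaller than ", params$minRoiPx,
         " px: likely a blank or failed capture")
  box
}

#' Crop an intensity matrix to a ROI box
#'
#' @param pixels numeric matrix.
#' @param box a [ROIBox-class] (0-based, half-open).
#' @return The cropped matrix.
#' @export
cropROI <- function(pixels, box) {
  stopifnot(is(box, "ROIBox"), box@right <= ncol(pixels),
            box@bottom <= nrow(pixels))
  pixels[(box@top + 1L):box@bottom, (box@left + 1L):box@right, drop = FALSE]
}

#' Bilateral filter parameters
#'
#' @param sigmaSpatial Gaussian standard deviation of the spatial kernel in
#'   pixels (default 5).
#' @param sigmaIntensity Gaussian standard deviation of the intensity
#'   (range) kernel, on intensities normalized to `[0, 1]` (default 0.1).
#' @param radius window half-width in pixels; defaults to
#'   `round(sigmaSpatial)`, an 11 x 11 window at the default sigma.
#' @return A list of class `filterParams`.
#' @export
filterParams <- function(sigmaSpatial = 5, sigmaIntensity = 0.1,
                         radius = round(sigmaSpatial)) {
  stopifnot(sigmaSpatial > 0, sigmaIntensity > 0, radius >= 1)
  structure(list(sigmaSpatial = sigmaSpatial,
                 sigmaIntensity = sigmaIntensity,
                 radius = as.integer(radius)),
            class = "filterParams")
}

#' Edge-preserving bilateral filter
#'
#' Each output pixel is the weighted mean of its neighbourhood, the weights
#' being the product of a spatial Gaussian and an intensity Gaussian, so
#' speckle is averaged out while step edges (whose intensity difference
#' dwarfs `sigmaIntensity`) are preserved. Neighbours outside the image are
#' excluded and the weights renormalized. Output values are convex
#' combinations of input values and therefore stay within the input range.
#'
#' @param pixels numeric matrix with intensities in `[0, 1]`.
#' @param params a [filterParams()] list.
#' @return The filtered matrix, same dimensions.
#' @export
bilateralFilter <- function(pixels, params = filterParams()) {
  stopifnot(is.matrix(pixels))
  if (!all(is.finite(pixels))) stop("non-finite pixel intensities")
  if (min(pixels) < 0 || max(pixels) > 1)
    stop("bilateralFilter expects intensities normalized to [0, 1]")
  .bilateralCpp(pixels, params$sigmaSpatial, params$sigmaIntensity,
                params$radius)
}

#' Rescale intensities to 0-255 integers
#'
#' Affinely maps the input range `[min, max]` onto `[0, 255]` and rounds
#' half-up. A constant (information-free) image maps to all zeros.
#'
#' @param pixels finite numeric matrix.
#' @return An integer matrix with values in 0-255.
#' @examples
#' rescaleToByte(matrix(c(0, 0.5, 1), 1))  # 0 128 255
#' @export
rescaleToByte <- function(pixels) {
  stopifnot(is.matrix(pixels))
  if (!all(is.finite(pixels))) stop("non-finite pixel intensities")
  lo <- min(pixels); hi <- max(pixels)
  if (hi == lo) {
    out <- matrix(0L, nrow(pixels), ncol(pixels))
    return(out)
  }
  out <- floor((pixels - lo) / (hi - lo) * 255 + 0.5)
  storage.mode(out) <- "integer"
  out
}
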