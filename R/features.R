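#' @include AllClasses.R
NULL

#' Gray-level co-occurrence specification
#'
#' @param levels number of gray levels after equal-width quantization of the
#'   0-255 byte range (default 32).
#' @param distancePx pair offset distance in pixels (default 1).
#' @param angles pair offset directions in radians (default the four
#'   standard directions 0, pi/4, pi/2, 3pi/4).
#' @param symmetric count each pair in both orders (default `TRUE`).
#' @return A list of class `glcmSpec`.
#' @export
glcmSpec <- function(levels = 32L, distancePx = 1L,
                     angles = c(0, pi / 4, pi / 2, 3 * pi / 4),
                     symmetric = TRUE) {
  stopifnot(levels >= 2L, distancePx >= 1L, length(angles) >= 1L)
  structure(list(levels = as.integer(levels),
                 distancePx = as.integer(distancePx),
                 angles = angles, symmetric = isTRUE(symmetric)),
            class = "glcmSpec")
}

#' Gray-level co-occurrence matrices
#'
#' Quantizes a byte window into `levels` equal-width bins and, for each
#' angle, counts gray-level pairs at the given pixel offset; symmetric
#' matrices add the transpose. Each matrix is normalized to sum 1 (a joint
#' probability over level pairs).
#'
#' @param window numeric matrix with intensities in 0-255, at least 2 x 2.
#' @param spec a [glcmSpec()] list.
#' @return A named list of `levels` x `levels` probability matrices, one
#'   per angle.
#' @examples
#' g <- glcm(matrix(c(0, 0, 255, 255), 2), glcmSpec(levels = 2, angles = 0))
#' g[["0"]]  # p(0,1) = p(1,0) = 0.5
#' @export
glcm <- function(window, spec = glcmSpec()) {
  stopifnot(is.matrix(window), nrow(window) >= 2L, ncol(window) >= 2L)
  L <- spec$levels
  q <- floor(pmin(pmax(window, 0), 255) * L / 256)
  storage.mode(q) <- "integer"
  h <- nrow(q); w <- ncol(q)
  d <- spec$distancePx
  out <- vector("list", length(spec$angles))
  names(out) <- format(spec$angles)
  for (k in seq_along(spec$angles)) {
    a <- spec$angles[k]
    dr <- -round(d * sin(a)); dc <- round(d * cos(a))
    rows <- seq_len(h)[(seq_len(h) + dr) >= 1L & (seq_len(h) + dr) <= h]
    cols <- seq_len(w)[(seq_len(w) + dc) >= 1L & (seq_len(w) + dc) <= w]
    if (length(rows) == 0L || length(cols) == 0L)
      stop("window smaller than the pair offset reach: no pairs at angle ",
           format(a))
    i <- q[rows, cols, drop = FALSE]
    j <- q[rows + dr, cols + dc, drop = FALSE]
    counts <- tabulate(i * L + j + 1L, nbins = L * L)
    P <- matrix(counts, L, L, byrow = TRUE)  # P[i+1, j+1]
    if (spec$symmetric) P <- P + t(P)
    out[[k]] <- P / sum(P)
  }
  out
}

# feature set for one normalized co-occurrence matrix
.glcmFeatures1 <- function(P) {
  L <- nrow(P)
  idx <- 0:(L - 1)
  I <- matrix(idx, L, L)
  J <- t(I)
  pi_ <- rowSums(P)
  pj_ <- colSums(P)
  mi <- sum(idx * pi_); mj <- sum(idx * pj_)
  si <- sqrt(sum((idx - mi)^2 * pi_)); sj <- sqrt(sum((idx - mj)^2 * pj_))
  pos <- P > 0
  c(asm = sum(P^2),
    contrast = sum((I - J)^2 * P),
    correlation = if (si * sj == 0) 0
                  else sum((I - mi) * (J - mj) * P) / (si * sj),
    dissimilarity = sum(abs(I - J) * P),
    entropy = -sum(P[pos] * log2(P[pos])),
    homogeneity = sum(P / (1 + (I - J)^2)))
}

#' Texture features from co-occurrence matrices
#'
#' Computes, per angle, the six co-occurrence features and reports their
#' mean over angles: angular second moment `sum(p^2)` (uniformity),
#' contrast `sum((i-j)^2 p)`, correlation
#' `sum((i-mu_i)(j-mu_j) p) / (sigma_i sigma_j)` (0 by convention when a
#' marginal variance vanishes), dissimilarity `sum(|i-j| p)`, entropy
#' `-sum(p log2 p)` in bits, and homogeneity (inverse difference moment)
#' `sum(p / (1 + (i-j)^2))`. Indices are the 0-based quantized gray levels.
#'
#' @param glcms list of normalized co-occurrence matrices from [glcm()].
#' @param homogeneityForm `"idm"` (inverse difference moment, the default
#'   `1/(1+(i-j)^2)` weights) or `"id"` (the `1/(1+|i-j|)` dialect).
#' @return Named numeric vector with elements `asm`, `contrast`,
#'   `correlation`, `dissimilarity`, `entropy`, `homogeneity`.
#' @export
textureFeatures <- function(glcms, homogeneityForm = c("idm", "id")) {
  homogeneityForm <- match.arg(homogeneityForm)
  stopifnot(is.list(glcms), length(glcms) >= 1L)
  feats <- vapply(glcms, function(P) {
    if (abs(sum(P) - 1) > 1e-9)
      stop("co-occurrence matrix is not normalized (sum != 1)")
    f <- .glcmFeatures1(P)
    if (homogeneityForm == "id") {
      L <- nrow(P); I <- matrix(0:(L - 1), L, L); J <- t(I)
      f["homogeneity"] <- sum(P / (1 + abs(I - J)))
    }
    f
  }, numeric(6))
  rowMeans(feats)
}

#' Mean gray level from the normalized histogram
#'
#' The mean of the 256-bin normalized gray-level distribution — numerically
#' the mean pixel intensity of the (rounded) byte window.
#'
#' @param window numeric matrix with intensities in 0-255.
#' @return The histogram mean.
#' @examples
#' histogramMean(matrix(17, 8, 8))  # 17
#' @export
histogramMean <- function(window) {
  stopifnot(is.matrix(window), length(window) > 0L)
  v <- round(pmin(pmax(window, 0), 255))
  freq <- tabulate(v + 1L, nbins = 256L) / length(v)
  sum((0:255) * freq)
}

#' All seven texture variables of a window
#'
#' Convenience wrapper: co-occurrence features plus the histogram mean, as
#' stored in a [MeasurementRecord-class].
#'
#' @param window byte-scale numeric matrix (typically the ROI).
#' @param spec a [glcmSpec()] list.
#' @return Named numeric vector of the seven features.
#' @export
textureVariables <- function(window, spec = glcmSpec()) {
  f <- textureFeatures(glcm(window, spec))
  c(f, histogram_mean = histogramMean(window))[.TEXTURE_VARIABLES]
}
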