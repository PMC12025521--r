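#' @include AllClasses.R
NULL

#' Pixel-to-centimetre calibration
#'
#' @param cmPerPx centimetres per pixel (isotropic); `NA` for uncalibrated
#'   scans, in which case measurements are reported in px/px^2 and flagged.
#' @param source where the calibration came from: `"dicom"` (PixelSpacing
#'   metadata), `"config"`, or `"none"`.
#' @return A list of class `calibration`.
#' @export
calibration <- function(cmPerPx = NA_real_,
                        source = c("none", "dicom", "config")) {
  source <- match.arg(source)
  if (source != "none") stopifnot(is.finite(cmPerPx), cmPerPx > 0)
  structure(list(cmPerPx = if (source == "none") NA_real_ else cmPerPx,
                 source = source, units = if (source == "none") "px"
                                          else "cm"),
            class = "calibration")
}

.calFactor <- function(cal) if (is.na(cal$cmPerPx)) 1 else cal$cmPerPx

#' Thickness between two detected interfaces
#'
#' The vertical distance between the interface depths of a superficial and
#' a deeper structure — the Y-axis / thickness family of variables (muscle
#' thicknesses, fat layer thicknesses).
#'
#' @param upper,lower [StructureDetection-class] objects; `upper` must be
#'   the more superficial one.
#' @param cal a [calibration()] list.
#' @return Thickness in cm (or px when uncalibrated).
#' @export
thickness <- function(upper, lower, cal = calibration()) {
  ru <- interfaceRow(upper); rl <- interfaceRow(lower)
  if (is.na(ru) || is.na(rl)) stop("cannot measure thickness: missing interface")
  if (rl < ru)
    stop("inverted interface order between '", structureId(upper),
         "' and '", structureId(lower), "'")
  (rl - ru) * .calFactor(cal)
}

#' Width of a measurement zone
#'
#' The X-axis family of variables: the width of the region of interest, as
#' fixed during the initial processing.
#'
#' @param roi a [ROIBox-class].
#' @param cal a [calibration()] list.
#' @return Width in cm (or px when uncalibrated).
#' @export
zoneWidth <- function(roi, cal = calibration()) {
  roiWidth(roi) * .calFactor(cal)
}

#' Rectangular area approximation
#'
#' @param height,width zone height and width (same units).
#' @return `height * width`.
#' @export
rectArea <- function(height, width) {
  stopifnot(height >= 0, width >= 0)
  height * width
}

#' Direct least-squares ellipse fit
#'
#' Fits an ellipse to scattered boundary points by the direct (non-iterative)
#' least-squares conic fit with the ellipse-specific constraint
#' `4AC - B^2 = 1`, using the numerically stable block decomposition of the
#' scatter matrix. The constraint guarantees the returned conic is an
#' ellipse whenever a solution exists.
#'
#' @param points n x 2 matrix of (row, col) boundary points, `n >= 6`, not
#'   collinear.
#' @return A list of class `ellipseParams` with elements `centerRow`,
#'   `centerCol`, `a` (major semi-axis), `b` (minor semi-axis, `a >= b`)
#'   and `theta` (orientation of the major axis in radians, in `[0, pi)`,
#'   measured from the column axis).
#' @examples
#' t <- seq(0, 2 * pi, length.out = 41)[-41]
#' pts <- cbind(50 + 20 * sin(t), 60 + 30 * cos(t))
#' fitEllipseDirect(pts)[c("a", "b")]  # 30, 20
#' @export
fitEllipseDirect <- function(points) {
  stopifnot(is.matrix(points), ncol(points) == 2L)
  if (nrow(points) < 6L) stop("ellipse fit needs at least 6 points")
  x <- points[, 2]  # col
  y <- points[, 1]  # row
  mx <- mean(x); my <- mean(y)
  x <- x - mx; y <- y - my  # centre for conditioning

  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  T1 <- tryCatch(-solve(S3, t(S2)), error = function(e)
    stop("degenerate point set: ellipse fit failed"))
  M <- S1 + S2 %*% T1
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)  # premultiply by inv(C)
  ev <- eigen(M)
  evec <- Re(ev$vectors)
  cond <- 4 * evec[1, ] * evec[3, ] - evec[2, ]^2
  ok <- which(cond > 0)
  if (length(ok) == 0L)
    stop("degenerate point set: no ellipse satisfies the fit constraint")
  a1 <- evec[, ok[1]]
  coef <- c(a1, as.vector(T1 %*% a1))  # A B C D E F on centred coords
  if (!all(is.finite(coef)))
    stop("degenerate point set: non-finite conic solution")

  A <- coef[1]; B <- coef[2]; C <- coef[3]
  D <- coef[4]; E <- coef[5]; F <- coef[6]
  den <- B^2 - 4 * A * C  # < 0 for an ellipse
  x0 <- (2 * C * D - B * E) / den
  y0 <- (2 * A * E - B * D) / den
  # semi-axes from the conic invariants
  num <- 2 * (A * E^2 + C * D^2 - B * D * E + den * F)
  s <- sqrt((A - C)^2 + B^2)
  axis1 <- -sqrt(num * (A + C + s)) / den
  axis2 <- -sqrt(num * (A + C - s)) / den
  if (!is.finite(axis1) || !is.finite(axis2))
    stop("degenerate point set: conic is not a real ellipse")
  theta <- if (B == 0 && A <= C) 0
           else if (B == 0) pi / 2
           else atan2(C - A - s, B)
  # axis1 belongs to direction theta; make a the major one
  a <- max(axis1, axis2); b <- min(axis1, axis2)
  if (axis2 > axis1) theta <- theta + pi / 2
  theta <- theta %% pi
  structure(list(centerRow = y0 + my, centerCol = x0 + mx,
                 a = a, b = b, theta = theta),
            class = "ellipseParams")
}

#' Elliptical area
#'
#' @param p an `ellipseParams` list from [fitEllipseDirect()] (axes in px).
#' @param cal a [calibration()] list.
#' @return `pi * a * b`, in cm^2 (or px^2 when uncalibrated).
#' @export
ellipseArea <- function(p, cal = calibration()) {
  stopifnot(p$a > 0, p$b > 0)
  pi * p$a * p$b * .calFactor(cal)^2
}

## --------------------------------------------------- per-category dispatch

# interface ids per scan category, superficial to deep
.STRUCTURES <- list(
  abdomen = c("skin", "fascia_superficial", "muscle_wall", "peritoneum",
              "peritoneal_deep"),
  leg = c("skin", "rectus_superficial", "rectus_deep", "vastus_deep")
)

.detectionByStructure <- function(detections) {
  ok <- detections[vapply(detections, function(d)
    !nzchar(detectionFlag(d)) || detectionFlag(d) == "refine_fallback",
    logical(1))]
  stats::setNames(ok, vapply(ok, structureId, character(1)))
}

# segment the elliptical muscle belly between two interface rows and fit an
# ellipse to its boundary; NULL when segmentation or the fit fails
.fitMuscleEllipse <- function(roiImage, rowTop, rowBottom, pad = 3L) {
  lo <- as.integer(floor(rowTop)) + pad
  hi <- as.integer(ceiling(rowBottom)) - pad
  if (hi - lo < 8L) return(NULL)
  sub <- roiImage[(lo + 1L):hi, , drop = FALSE]
  thr <- EBImage::otsu(EBImage::Image(sub / 255), range = c(0, 1),
                       levels = 256L)
  kern <- EBImage::makeBrush(7L, shape = "disc")
  m <- EBImage::opening(EBImage::closing((sub / 255 > thr) * 1, kern), kern)
  lbl <- EBImage::bwlabel(m > 0.5)
  if (max(lbl) == 0) return(NULL)
  comp <- lbl == which.max(tabulate(lbl[lbl > 0]))
  oc <- EBImage::ocontour(EBImage::bwlabel(comp))[[1]]
  if (nrow(oc) < 6L) return(NULL)
  pts <- cbind(oc[, 1] + lo, oc[, 2])
  tryCatch(fitEllipseDirect(pts), error = function(e) NULL)
}

#' Measure the clinical length and area variables of a scan
#'
#' Converts validated detections into the variable set of the scan's
#' category. Abdominal scans yield the three fat thicknesses (superficial
#' subcutaneous = fascia minus skin, total subcutaneous = muscle wall minus
#' skin, peritoneal = deep peritoneal boundary minus peritoneum). Leg scans
#' yield Y-axis (thickness) and X-axis (ROI width) for the anterior rectus
#' (rectus femoris) and vastus intermedius plus their areas; in the
#' transverse plane the rectus area uses the direct least-squares ellipse
#' fit of the segmented muscle belly when it succeeds (rectangular fallback
#' otherwise, with the choice recorded in the provenance), all other areas
#' are rectangular. Variables whose interfaces were not detected are absent
#' from the record — never zero — and the record is flagged incomplete.
#'
#' @param detections list of [StructureDetection-class] (after
#'   [validateOrder()] and [refineContour()]).
#' @param roi the scan's [ROIBox-class] (image coordinates).
#' @param scanDescriptor the scan's [ScanDescriptor-class].
#' @param cal a [calibration()] list.
#' @param roiImage optional byte-scale ROI matrix; required for the
#'   elliptical area fit, otherwise the rectangular fallback is used.
#' @param imageId identifier stored in the record.
#' @return A [MeasurementRecord-class].
#' @export
measureStructures <- function(detections, roi, scanDescriptor,
                              cal = calibration(), roiImage = NULL,
                              imageId = "scan") {
  byId <- .detectionByStructure(detections)
  if (length(byId) == 0L)
    stop("no valid detections: cannot build a measurement record")
  expected <- .STRUCTURES[[region(scanDescriptor)]]
  vals <- numeric(0)
  prov <- list(
    templates = vapply(detections, structureId, character(1)),
    scores = vapply(detections, matchScore, numeric(1)),
    variant_index = vapply(detections, function(d) d@match@variantIndex,
                           integer(1)),
    match_method = if (length(detections)) detections[[1]]@match@method
                   else "zncc",
    calibration_source = cal$source)
  flags <- character(0)
  missing <- setdiff(expected, names(byId))
  if (length(missing))
    flags <- c(flags, paste0("incomplete: missing ",
                             paste(missing, collapse = ", ")))

  has <- function(...) all(c(...) %in% names(byId))
  thick <- function(a, b) thickness(byId[[a]], byId[[b]], cal)

  if (region(scanDescriptor) == "abdomen") {
    if (has("skin", "fascia_superficial"))
      vals["Superficial Subcutaneous Fat"] <- thick("skin",
                                                    "fascia_superficial")
    if (has("skin", "muscle_wall"))
      vals["Total Subcutaneous Fat"] <- thick("skin", "muscle_wall")
    if (has("peritoneum", "peritoneal_deep"))
      vals["Peritoneal Fat"] <- thick("peritoneum", "peritoneal_deep")
  } else {
    wz <- zoneWidth(roi, cal)
    if (has("skin", "rectus_superficial") &&
        plane(scanDescriptor) == "longitudinal")
      vals["Subcutaneous Fat"] <- thick("skin", "rectus_superficial")
    if (has("rectus_superficial", "rectus_deep")) {
      yR <- thick("rectus_superficial", "rectus_deep")
      vals["Y-axis Anterior Rectus"] <- yR
      vals["X-axis Anterior Rectus"] <- wz
      fit <- NULL
      if (plane(scanDescriptor) == "transverse" && !is.null(roiImage))
        fit <- .fitMuscleEllipse(roiImage,
                                 interfaceRow(byId[["rectus_superficial"]]),
                                 interfaceRow(byId[["rectus_deep"]]))
      if (!is.null(fit)) {
        vals["Anterior Rectus Area"] <- ellipseArea(fit, cal)
        prov$rectus_area_approx <- "ellipse"
        prov$rectus_ellipse <- fit[c("centerRow", "centerCol", "a", "b",
                                     "theta")]
      } else {
        vals["Anterior Rectus Area"] <- rectArea(yR, wz)
        prov$rectus_area_approx <- "rectangle"
        if (plane(scanDescriptor) == "transverse")
          flags <- c(flags, "rectus ellipse fit unavailable: rectangle used")
      }
    }
    if (has("rectus_deep", "vastus_deep")) {
      yV <- thick("rectus_deep", "vastus_deep")
      vals["Y-axis Vastus Intermedius"] <- yV
      vals["X-axis Vastus Intermedius"] <- wz
      vals["Vastus Intermedius Area"] <- rectArea(yV, wz)
      prov$vastus_area_approx <- "rectangle"
    }
  }
  MeasurementRecord(imageId = imageId, descriptor = scanDescriptor,
                    values = vals, units = cal$units,
                    provenance = prov, flags = flags)
}
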