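#' @include AllGenerics.R
NULL

.REGIONS <- c("abdomen", "leg")
.PLANES  <- c("longitudinal", "transverse")

## ---------------------------------------------------------------- descriptors

#' Scan descriptor: anatomical region and imaging plane
#'
#' Every scan belongs to one of four categories — longitudinal or transverse
#' scans of the abdomen or the thigh ("leg"). The category decides which
#' interface templates are searched for and which length/area variables are
#' reported.
#'
#' @slot region `"abdomen"` or `"leg"`.
#' @slot plane `"longitudinal"` or `"transverse"`.
#' @slot code the raw annotation the category was parsed from (may be `""`).
#'
#' @param region,plane,code see slots.
#' @return A `ScanDescriptor` object.
#' @examples
#' ScanDescriptor("leg", "transverse")
#' @export ScanDescriptor
#' @exportClass ScanDescriptor
ScanDescriptor <- setClass(
  "ScanDescriptor",
  slots = c(region = "character", plane = "character", code = "character")
)

setMethod("initialize", "ScanDescriptor",
          function(.Object, region, plane, code = "", ...) {
  .Object <- callNextMethod(.Object, region = as.character(region),
                            plane = as.character(plane),
                            code = as.character(code), ...)
  validObject(.Object)
  .Object
})

setValidity("ScanDescriptor", function(object) {
  msg <- NULL
  if (length(object@region) != 1L || !(object@region %in% .REGIONS))
    msg <- c(msg, sprintf("region must be one of: %s",
                          paste(.REGIONS, collapse = ", ")))
  if (length(object@plane) != 1L || !(object@plane %in% .PLANES))
    msg <- c(msg, sprintf("plane must be one of: %s",
                          paste(.PLANES, collapse = ", ")))
  if (is.null(msg)) TRUE else msg
})

#' @describeIn ScanDescriptor region accessor
#' @param x a `ScanDescriptor`
#' @export
setMethod("region", "ScanDescriptor", function(x) x@region)

#' @describeIn ScanDescriptor plane accessor
#' @export
setMethod("plane", "ScanDescriptor", function(x) x@plane)

setMethod("show", "ScanDescriptor", function(object) {
  cat(sprintf("ScanDescriptor: %s / %s%s\n", object@region, object@plane,
              if (nzchar(object@code)) sprintf(" (code '%s')", object@code)
              else ""))
})

setClassUnion("ScanDescriptorOrNULL", c("ScanDescriptor", "NULL"))

## --------------------------------------------------------------------- boxes

#' Rectangular pixel box (0-based, half-open)
#'
#' All pixel coordinates in the package are row-major, 0-based and half-open:
#' a box covers columns `[left, right)` and rows `[top, bottom)`. The same
#' class describes the region of interest of a scan and the bounding box of a
#' template match.
#'
#' @slot left,right,top,bottom integer pixel indices, `left < right`,
#'   `top < bottom`.
#'
#' @param left,right,top,bottom see slots.
#' @return A `ROIBox`.
#' @examples
#' b <- ROIBox(30, 70, 20, 60)
#' roiWidth(b)   # 40
#' roiHeight(b)  # 40
#' @export ROIBox
#' @exportClass ROIBox
ROIBox <- setClass(
  "ROIBox",
  slots = c(left = "integer", right = "integer",
            top = "integer", bottom = "integer")
)

setMethod("initialize", "ROIBox",
          function(.Object, left, right, top, bottom, ...) {
  .Object <- callNextMethod(.Object,
                            left = as.integer(left), right = as.integer(right),
                            top = as.integer(top), bottom = as.integer(bottom),
                            ...)
  validObject(.Object)
  .Object
})

setValidity("ROIBox", function(object) {
  msg <- NULL
  for (s in c("left", "right", "top", "bottom"))
    if (length(slot(object, s)) != 1L || is.na(slot(object, s)))
      msg <- c(msg, sprintf("'%s' must be a single non-missing integer", s))
  if (is.null(msg)) {
    if (object@left < 0L || object@top < 0L)
      msg <- c(msg, "box indices must be non-negative")
    if (object@left >= object@right)
      msg <- c(msg, "left must be < right")
    if (object@top >= object@bottom)
      msg <- c(msg, "top must be < bottom")
  }
  if (is.null(msg)) TRUE else msg
})

#' @describeIn ROIBox box width in pixels
#' @param x a `ROIBox`
#' @export
roiWidth <- function(x) x@right - x@left

#' @describeIn ROIBox box height in pixels
#' @export
roiHeight <- function(x) x@bottom - x@top

#' @describeIn ROIBox left/right/top/bottom coordinates as a named integer
#'   vector
#' @export
roiCoords <- function(x)
  c(left = x@left, right = x@right, top = x@top, bottom = x@bottom)

setMethod("show", "ROIBox", function(object) {
  cat(sprintf("ROIBox: cols [%d, %d) x rows [%d, %d)  (%d x %d px)\n",
              object@left, object@right, object@top, object@bottom,
              roiWidth(object), roiHeight(object)))
})

## --------------------------------------------------------------------- scans

#' A grayscale B-mode ultrasound scan
#'
#' Container for one 2-D grayscale scan: the intensity matrix (rows = depth),
#' optional isotropic pixel spacing in cm, the source path and the parsed
#' scan descriptor (when known).
#'
#' @slot pixels numeric matrix of intensities, typically 0-255.
#' @slot pixelSpacingCm cm per pixel (isotropic); `NA` when uncalibrated.
#' @slot sourcePath where the scan was read from (`""` for synthetic scans).
#' @slot descriptor a [ScanDescriptor-class] or `NULL`.
#'
#' @param pixels,pixelSpacingCm,sourcePath,descriptor see slots.
#' @return An `UltrasoundScan`.
#' @examples
#' s <- UltrasoundScan(matrix(0, 64, 64))
#' dim(pixels(s))
#' @export UltrasoundScan
#' @exportClass UltrasoundScan
UltrasoundScan <- setClass(
  "UltrasoundScan",
  slots = c(pixels = "matrix", pixelSpacingCm = "numeric",
            sourcePath = "character", descriptor = "ScanDescriptorOrNULL")
)

setMethod("initialize", "UltrasoundScan",
          function(.Object, pixels, pixelSpacingCm = NA_real_,
                   sourcePath = "", descriptor = NULL, ...) {
  .Object <- callNextMethod(.Object, pixels = pixels,
                            pixelSpacingCm = as.numeric(pixelSpacingCm),
                            sourcePath = as.character(sourcePath),
                            descriptor = descriptor, ...)
  validObject(.Object)
  .Object
})

setValidity("UltrasoundScan", function(object) {
  msg <- NULL
  p <- object@pixels
  if (!is.numeric(p)) msg <- c(msg, "pixels must be numeric")
  if (nrow(p) < 32L || ncol(p) < 32L)
    msg <- c(msg, "scan must be at least 32 x 32 pixels")
  if (is.numeric(p) && !all(is.finite(p)))
    msg <- c(msg, "all pixel intensities must be finite")
  sp <- object@pixelSpacingCm
  if (length(sp) != 1L) msg <- c(msg, "pixelSpacingCm must be length 1")
  else if (!is.na(sp) && sp <= 0)
    msg <- c(msg, "pixelSpacingCm must be > 0 when present")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn UltrasoundScan intensity matrix accessor
#' @param x an `UltrasoundScan`
#' @export
setMethod("pixels", "UltrasoundScan", function(x) x@pixels)

#' @describeIn UltrasoundScan pixel spacing (cm/px, `NA` if uncalibrated)
#' @export
setMethod("pixelSpacing", "UltrasoundScan", function(x) x@pixelSpacingCm)

#' @describeIn UltrasoundScan scan descriptor accessor (may be `NULL`)
#' @export
setMethod("descriptor", "UltrasoundScan", function(x) x@descriptor)

setMethod("show", "UltrasoundScan", function(object) {
  cat(sprintf("UltrasoundScan: %d x %d px, spacing %s\n",
              nrow(object@pixels), ncol(object@pixels),
              if (is.na(object@pixelSpacingCm)) "unknown"
              else sprintf("%.4g cm/px", object@pixelSpacingCm)))
  if (!is.null(object@descriptor)) show(object@descriptor)
  if (nzchar(object@sourcePath))
    cat("  source:", object@sourcePath, "\n")
})

## ----------------------------------------------------------------- templates

#' Library of anatomical interface templates
#'
#' Small grayscale patches, one per anatomical interface per scan category,
#' used by the template-matching detector. `manifest` holds one row per patch
#' (`structure_id`, `region`, `plane`, `order_index`, `filename`);
#' `order_index` encodes the superficial-to-deep anatomical ordering and is
#' unique within a (region, plane) category. `patches` holds the intensity
#' matrices in manifest order.
#'
#' @slot manifest data.frame as described above.
#' @slot patches list of numeric matrices, one per manifest row.
#'
#' @param manifest,patches see slots.
#' @return A `TemplateSet`.
#' @seealso [loadTemplateLibrary()], [extractTemplates()]
#' @export TemplateSet
#' @exportClass TemplateSet
TemplateSet <- setClass(
  "TemplateSet",
  slots = c(manifest = "data.frame", patches = "list")
)

setValidity("TemplateSet", function(object) {
  msg <- NULL
  need <- c("structure_id", "region", "plane", "order_index", "filename")
  if (!all(need %in% names(object@manifest)))
    msg <- c(msg, sprintf("manifest must have columns: %s",
                          paste(need, collapse = ", ")))
  else {
    m <- object@manifest
    if (nrow(m) != length(object@patches))
      msg <- c(msg, "one patch required per manifest row")
    key <- paste(m$region, m$plane, m$structure_id)
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate (region, plane, structure_id) entries")
    okey <- paste(m$region, m$plane, m$order_index)
    if (anyDuplicated(okey))
      msg <- c(msg, "order_index must be unique within a (region, plane)")
    if (!all(m$region %in% .REGIONS) || !all(m$plane %in% .PLANES))
      msg <- c(msg, "manifest region/plane outside the four scan categories")
    bad <- !vapply(object@patches, function(p)
      is.matrix(p) && is.numeric(p) && all(is.finite(p)), logical(1))
    if (any(bad)) msg <- c(msg, "patches must be finite numeric matrices")
  }
  if (is.null(msg)) TRUE else msg
})

#' @describeIn TemplateSet number of templates
#' @param object a `TemplateSet`
#' @export
setMethod("length", "TemplateSet", function(x) nrow(x@manifest))

#' @describeIn TemplateSet subset of templates for one scan category, ordered
#'   superficial to deep (increasing `order_index`)
#' @param x a `TemplateSet`
#' @param descriptor a [ScanDescriptor-class]
#' @export
setMethod("templatesFor", "TemplateSet", function(x, descriptor) {
  keep <- x@manifest$region == region(descriptor) &
          x@manifest$plane == plane(descriptor)
  idx <- which(keep)[order(x@manifest$order_index[keep])]
  TemplateSet(manifest = x@manifest[idx, , drop = FALSE],
              patches = x@patches[idx])
})

setMethod("show", "TemplateSet", function(object) {
  cat(sprintf("TemplateSet: %d templates\n", nrow(object@manifest)))
  if (nrow(object@manifest))
    print(object@manifest[, c("structure_id", "region", "plane",
                              "order_index")])
})

## ---------------------------------------------------------------- detections

#' One template-matching result
#'
#' @slot structureId which anatomical interface the template stands for.
#' @slot score match score; Pearson correlation in `[-1, 1]` under the
#'   default normalized method. `NA` for a failed detection.
#' @slot bbox bounding box of the matched window ([ROIBox-class]) in ROI
#'   coordinates, or `NULL` when the match failed.
#' @slot variantIndex 0 for the original template, > 0 when a scale or
#'   contrast fallback variant matched.
#' @slot method `"zncc"` or `"ccorr"` (the raw correlation flavour).
#'
#' @param structureId,score,bbox,variantIndex,method see slots.
#' @return A `MatchResult`.
#' @export MatchResult
#' @exportClass MatchResult
MatchResult <- setClass(
  "MatchResult",
  slots = c(structureId = "character", score = "numeric", bbox = "ANY",
            variantIndex = "integer", method = "character")
)

setMethod("initialize", "MatchResult",
          function(.Object, structureId, score, bbox = NULL,
                   variantIndex = 0L, method = "zncc", ...) {
  callNextMethod(.Object, structureId = as.character(structureId),
                 score = as.numeric(score), bbox = bbox,
                 variantIndex = as.integer(variantIndex),
                 method = as.character(method), ...)
})

setValidity("MatchResult", function(object) {
  msg <- NULL
  if (!is.null(object@bbox) && !is(object@bbox, "ROIBox"))
    msg <- c(msg, "bbox must be a ROIBox or NULL")
  if (length(object@score) != 1L)
    msg <- c(msg, "score must be length 1")
  if (is.null(msg)) TRUE else msg
})

#' A detected anatomical structure
#'
#' A [MatchResult-class] plus the refined contour and the representative
#' interface depth. `contour` is an n x 2 matrix of (row, col) points in ROI
#' coordinates (0-based); `interfaceRow` is the structure's boundary depth,
#' initially the matched window's centre row and, after
#' [refineContour()], the median row of the contour's upper edge. A
#' non-empty `flag` marks failed or demoted detections
#' (`"detection_failure"`, `"order_violation"`, `"refine_fallback"`).
#'
#' @slot match a [MatchResult-class].
#' @slot contour n x 2 numeric matrix of (row, col) points.
#' @slot interfaceRow numeric; `NA` for failed detections.
#' @slot flag character; `""` for a clean detection.
#'
#' @param match,contour,interfaceRow,flag see slots.
#' @return A `StructureDetection`.
#' @export StructureDetection
#' @exportClass StructureDetection
StructureDetection <- setClass(
  "StructureDetection",
  slots = c(match = "MatchResult", contour = "matrix",
            interfaceRow = "numeric", flag = "character")
)

setMethod("initialize", "StructureDetection",
          function(.Object, match, contour = matrix(numeric(0), 0, 2),
                   interfaceRow = NA_real_, flag = "", ...) {
  callNextMethod(.Object, match = match, contour = contour,
                 interfaceRow = as.numeric(interfaceRow),
                 flag = as.character(flag), ...)
})

setValidity("StructureDetection", function(object) {
  msg <- NULL
  if (ncol(object@contour) != 2L)
    msg <- c(msg, "contour must be an n x 2 (row, col) matrix")
  if (length(object@interfaceRow) != 1L)
    msg <- c(msg, "interfaceRow must be length 1")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn StructureDetection structure identifier
#' @param x a `StructureDetection`
#' @export
setMethod("structureId", "StructureDetection",
          function(x) x@match@structureId)

#' @describeIn StructureDetection match score
#' @export
setMethod("matchScore", "StructureDetection", function(x) x@match@score)

#' @describeIn StructureDetection matched bounding box (ROI coordinates)
#' @export
setMethod("bbox", "StructureDetection", function(x) x@match@bbox)

#' @describeIn StructureDetection representative boundary depth (ROI row)
#' @export
setMethod("interfaceRow", "StructureDetection", function(x) x@interfaceRow)

#' @describeIn StructureDetection refined contour points
#' @export
setMethod("contour", "StructureDetection", function(x) x@contour)

#' @describeIn StructureDetection status flag (`""` when clean)
#' @export
setMethod("detectionFlag", "StructureDetection", function(x) x@flag)

setMethod("show", "StructureDetection", function(object) {
  cat(sprintf("StructureDetection '%s': score %.3f, interface row %s%s\n",
              object@match@structureId, object@match@score,
              format(object@interfaceRow),
              if (nzchar(object@flag)) paste0(" [", object@flag, "]")
              else ""))
})

## -------------------------------------------------------------- measurements

#' Measurements extracted from one scan
#'
#' The per-scan result of the pipeline: the applicable length and area
#' variables for the scan category (named as in the clinical variable table,
#' e.g. `"Y-axis Anterior Rectus"`), the seven texture variables computed on
#' the ROI, the measurement units, and provenance (templates used, match
#' scores, area approximations).
#'
#' @slot imageId identifier of the scan (file stem for on-disk scans).
#' @slot descriptor the scan's [ScanDescriptor-class].
#' @slot values named numeric vector; lengths in cm, areas in cm^2 (or px,
#'   px^2 when uncalibrated). Variables that could not be measured are
#'   absent, never zero.
#' @slot units `"cm"` or `"px"`.
#' @slot texture named numeric vector of texture features.
#' @slot provenance list of processing details.
#' @slot flags character vector of non-fatal issues (e.g. failed stages).
#'
#' @param imageId,descriptor,values,units,texture,provenance,flags see slots.
#' @return A `MeasurementRecord`.
#' @export MeasurementRecord
#' @exportClass MeasurementRecord
MeasurementRecord <- setClass(
  "MeasurementRecord",
  slots = c(imageId = "character", descriptor = "ScanDescriptorOrNULL",
            values = "numeric", units = "character", texture = "numeric",
            provenance = "list", flags = "character")
)

setMethod("initialize", "MeasurementRecord",
          function(.Object, imageId, descriptor = NULL,
                   values = numeric(0), units = "cm",
                   texture = numeric(0), provenance = list(),
                   flags = character(0), ...) {
  .Object <- callNextMethod(.Object, imageId = as.character(imageId),
                            descriptor = descriptor, values = values,
                            units = units, texture = texture,
                            provenance = provenance, flags = flags, ...)
  validObject(.Object)
  .Object
})

setValidity("MeasurementRecord", function(object) {
  msg <- NULL
  if (!(object@units %in% c("cm", "px")))
    msg <- c(msg, "units must be 'cm' or 'px'")
  if (length(object@values) && is.null(names(object@values)))
    msg <- c(msg, "values must be named")
  v <- object@values
  if (length(v) && any(v[is.finite(v)] < 0))
    msg <- c(msg, "lengths and areas must be non-negative")
  tx <- object@texture
  if (length(tx)) {
    if (!is.null(tx["asm"]) && !is.na(tx["asm"]) &&
        (tx[["asm"]] <= 0 || tx[["asm"]] > 1))
      msg <- c(msg, "asm must lie in (0, 1]")
    if (!is.na(tx["entropy"] %||% NA) && tx[["entropy"]] < -1e-12)
      msg <- c(msg, "entropy must be >= 0")
  }
  if (is.null(msg)) TRUE else msg
})

#' @describeIn MeasurementRecord named length/area values
#' @param x a `MeasurementRecord`
#' @export
setMethod("measurementValues", "MeasurementRecord", function(x) x@values)

#' @describeIn MeasurementRecord named texture features
#' @export
setMethod("textureValues", "MeasurementRecord", function(x) x@texture)

#' @describeIn MeasurementRecord measurement units (`"cm"` or `"px"`)
#' @export
setMethod("measurementUnits", "MeasurementRecord", function(x) x@units)

#' @describeIn MeasurementRecord the scan's descriptor
#' @export
setMethod("descriptor", "MeasurementRecord", function(x) x@descriptor)

setMethod("show", "MeasurementRecord", function(object) {
  cat(sprintf("MeasurementRecord '%s' (%s)\n", object@imageId, object@units))
  if (!is.null(object@descriptor))
    cat(sprintf("  %s / %s\n", region(object@descriptor),
                plane(object@descriptor)))
  if (length(object@values)) {
    for (nm in names(object@values))
      cat(sprintf("  %-32s %.4f\n", nm, object@values[[nm]]))
  } else cat("  (no length/area values)\n")
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = "; "), "\n")
})

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

## ----------------------------------------------------------------- agreement

#' Bland-Altman agreement between two measurement methods
#'
#' @slot variable name of the compared variable.
#' @slot bias mean difference (first method minus second).
#' @slot loaLow,loaHigh 95% limits of agreement, `bias -/+ 1.96 * sd(d)`.
#' @slot ciBias 95% confidence interval of the bias.
#' @slot n number of pairs.
#' @slot points data.frame with columns `mean` and `difference`, one row per
#'   pair (the Bland-Altman plot data).
#'
#' @param variable,bias,loaLow,loaHigh,ciBias,n,points see slots.
#' @return An `AgreementResult`.
#' @seealso [blandAltman()]
#' @export AgreementResult
#' @exportClass AgreementResult
AgreementResult <- setClass(
  "AgreementResult",
  slots = c(variable = "character", bias = "numeric", loaLow = "numeric",
            loaHigh = "numeric", ciBias = "numeric", n = "integer",
            points = "data.frame")
)

setValidity("AgreementResult", function(object) {
  msg <- NULL
  if (!(object@loaLow <= object@bias && object@bias <= object@loaHigh))
    msg <- c(msg, "limits of agreement must bracket the bias")
  if (object@n != nrow(object@points))
    msg <- c(msg, "n must match the number of plot points")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "AgreementResult", function(object) {
  cat(sprintf("AgreementResult '%s' (n = %d)\n", object@variable, object@n))
  cat(sprintf("  bias  %.5g  [95%% CI %.5g, %.5g]\n", object@bias,
              object@ciBias[1], object@ciBias[2]))
  cat(sprintf("  LoA   [%.5g, %.5g]\n", object@loaLow, object@loaHigh))
})
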