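#' @include AllClasses.R
NULL

#' Template-matching configuration
#'
#' @param acceptScore minimum normalized correlation for a match to be
#'   accepted (default 0.60).
#' @param variantScales scale factors for fallback template variants
#'   (bilinear resampling; default `c(0.9, 1.1)`).
#' @param variantContrasts contrast factors `c` for fallback variants,
#'   applied as `clip(128 + c * (p - 128))` (default `c(0.8, 1.2)`).
#' @param directionOrder which search direction wins ties when both accept a
#'   structure with equal score: `"bottom_up_first"` (default, the deep-to-
#'   superficial pass) or `"top_down_first"`.
#' @param method correlation flavour: `"zncc"` (zero-mean normalized
#'   cross-correlation, the default) or `"ccorr"` (raw cross-correlation,
#'   kept for fidelity experiments; brightness-biased).
#' @return A list of class `matchConfig`.
#' @export
matchConfig <- function(acceptScore = 0.60, variantScales = c(0.9, 1.1),
                        variantContrasts = c(0.8, 1.2),
                        directionOrder = c("bottom_up_first",
                                           "top_down_first"),
                        method = c("zncc", "ccorr")) {
  directionOrder <- match.arg(directionOrder)
  method <- match.arg(method)
  stopifnot(acceptScore > 0, acceptScore < 1, all(variantScales > 0))
  structure(list(acceptScore = acceptScore, variantScales = variantScales,
                 variantContrasts = variantContrasts,
                 directionOrder = directionOrder, method = method),
            class = "matchConfig")
}

#' Match a template patch against an image
#'
#' Slides the patch over every valid offset. Under the default `"zncc"`
#' method the score at each offset is the zero-mean normalized
#' cross-correlation (the Pearson correlation of the window with the
#' patch), which is invariant to affine intensity changes; `"ccorr"` gives
#' the raw correlation sum. Returns the best-scoring offset. Offset ties
#' resolve to the first offset in column-major order, so results are fully
#' deterministic.
#'
#' @param image numeric matrix (byte scale).
#' @param patch numeric matrix, strictly smaller than `image` in both
#'   dimensions; must have non-zero variance under `"zncc"`.
#' @param method `"zncc"` or `"ccorr"`.
#' @param structureId optional id recorded in the result.
#' @return A [MatchResult-class]; its `bbox` is 0-based half-open.
#' @examples
#' img <- matrix(runif(64 * 64) * 255, 64)
#' res <- matchTemplate(img, img[11:20, 21:35])
#' roiCoords(bbox(res))  # top 10, left 20 (0-based)
#' @export
matchTemplate <- function(image, patch, method = c("zncc", "ccorr"),
                          structureId = "") {
  method <- match.arg(method)
  stopifnot(is.matrix(image), is.matrix(patch))
  if (nrow(patch) >= nrow(image) || ncol(patch) >= ncol(image))
    stop("patch must be strictly smaller than the image in both dimensions")
  if (method == "zncc" && stats::var(as.vector(patch)) == 0)
    stop("degenerate template: patch has zero variance")
  scores <- .matchScores(image, patch, method == "zncc")
  ind <- which.max(scores)
  r0 <- (ind - 1L) %% nrow(scores)        # 0-based offsets
  c0 <- (ind - 1L) %/% nrow(scores)
  MatchResult(structureId = structureId, score = scores[ind],
              bbox = ROIBox(left = c0, right = c0 + ncol(patch),
                            top = r0, bottom = r0 + nrow(patch)),
              variantIndex = 0L, method = method)
}

#' Generate fallback variants of a template
#'
#' Ordered, deterministic variant list: the original patch first, then one
#' bilinearly rescaled copy per scale factor, then one contrast-remapped
#' copy per contrast factor (`clip(128 + c * (p - 128))`). Variants that
#' would shrink below 3 x 3 pixels are skipped with a message.
#'
#' @param patch numeric matrix (byte scale).
#' @param config a [matchConfig()] list.
#' @return A list of numeric matrices; names identify the variants.
#' @export
generateVariants <- function(patch, config = matchConfig()) {
  stopifnot(is.matrix(patch))
  out <- list(original = patch)
  for (s in config$variantScales) {
    if (s == 1) next
    nr <- round(nrow(patch) * s); nc <- round(ncol(patch) * s)
    if (nr < 3L || nc < 3L) {
      message("skipping scale variant ", s, ": patch would shrink below 3x3")
      next
    }
    v <- EBImage::resize(patch, w = nr, h = nc, filter = "bilinear")
    out[[sprintf("scale_%g", s)]] <- pmin(pmax(round(v), 0), 255)
  }
  for (cc in config$variantContrasts) {
    if (cc == 1) { out[[sprintf("contrast_%g", cc)]] <- patch; next }
    v <- pmin(pmax(round(128 + cc * (patch - 128)), 0), 255)
    out[[sprintf("contrast_%g", cc)]] <- v
  }
  out
}

# best accepted match for one structure in one direction; the admissible
# depth band constrains the window-centre (interface) row to the open
# interval (minInterface, maxInterface). NULL if nothing accepted.
#
# Because different anatomical interfaces can look locally alike, the scan
# direction is load-bearing: the pass walks the depth axis in its direction
# and locks onto the FIRST contiguous run of depths whose best column score
# reaches the acceptance threshold, taking the run's score peak. A global
# arg-max would be free to lock onto any similar-looking deeper (or
# shallower) interface. The run's far end is also reported so that the
# caller can restrict the next structure's search beyond the whole echo
# band, not just beyond its peak (a bright interface scores above the
# threshold for several neighbouring offsets).
#
# Returns list(match = MatchResult, bandEnd = interface row at the far end
# of the accepted run) or NULL if no variant produces an acceptable match.
.matchInBand <- function(image, variants, config, structureId,
                         direction = c("down", "up"),
                         minInterface = -Inf, maxInterface = Inf) {
  direction <- match.arg(direction)
  H <- nrow(image)
  for (vi in seq_along(variants)) {
    v <- variants[[vi]]
    vr <- nrow(v); vc <- ncol(v)
    rh <- (vr - 1L) %/% 2L
    lo <- 0L
    if (is.finite(minInterface)) lo <- max(lo, floor(minInterface) + 1L - rh)
    hi <- H - vr
    if (is.finite(maxInterface)) hi <- min(hi, ceiling(maxInterface) - 1L - rh)
    if (lo > hi || vc >= ncol(image)) next
    if (stats::var(as.vector(v)) == 0) next
    sub <- image[(lo + 1L):(hi + vr), , drop = FALSE]
    scores <- .matchScores(sub, v, config$method == "zncc")
    rowBest <- apply(scores, 1L, max)
    supra <- rowBest >= config$acceptScore
    if (!any(supra)) next
    runs <- rle(supra)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    hit <- if (direction == "down") which(runs$values)[1]
           else rev(which(runs$values))[1]
    run <- starts[hit]:ends[hit]
    r1 <- run[which.max(rowBest[run])]
    c1 <- which.max(scores[r1, ])
    sc <- scores[r1, c1]
    r0 <- as.integer(lo) + r1 - 1L
    c0 <- c1 - 1L
    bandEndOffset <- if (direction == "down") ends[hit] else starts[hit]
    return(list(
      match = MatchResult(structureId = structureId, score = sc,
                          bbox = ROIBox(left = c0, right = c0 + vc,
                                        top = r0, bottom = r0 + vr),
                          variantIndex = vi - 1L, method = config$method),
      bandEnd = as.integer(lo) + bandEndOffset - 1L + rh))
  }
  NULL
}

.interfaceFromBbox <- function(b) b@top + (roiHeight(b) - 1L) %/% 2L

#' Detect anatomical structures in a ROI by bidirectional template matching
#'
#' For the scan category of `scanDescriptor`, searches for each interface
#' template in anatomical order, twice: top-down (superficial to deep, each
#' structure restricted to depths strictly below the previously accepted
#' interface) and bottom-up (deep to superficial, restricted to depths
#' strictly above). Each pass walks the depth axis in its own direction and
#' accepts the first depth whose score reaches `acceptScore`, refined to
#' the local score maximum — this is what lets the detector tell apart
#' interfaces that look locally alike. Within a structure, fallback
#' variants ([generateVariants()]) are tried in order and the first one
#' producing an acceptable match is used. Per structure the direction with
#' the higher accepted score wins. Structures that no variant detects in
#' either direction are returned flagged `"detection_failure"` rather than
#' aborting the scan.
#'
#' The interface depth of each detection is provisionally the matched
#' window's centre row; [refineContour()] later replaces it with the
#' contour-based estimate.
#'
#' @param roiImage byte-scale numeric matrix (the preprocessed ROI).
#' @param templates a [TemplateSet-class].
#' @param scanDescriptor the scan's [ScanDescriptor-class].
#' @param config a [matchConfig()] list.
#' @return A list of [StructureDetection-class], in superficial-to-deep
#'   template order.
#' @export
detectStructures <- function(roiImage, templates, scanDescriptor,
                             config = matchConfig()) {
  stopifnot(is.matrix(roiImage), is(templates, "TemplateSet"))
  tset <- templatesFor(templates, scanDescriptor)
  nS <- length(tset)
  if (nS == 0L)
    stop("no templates available for ", region(scanDescriptor), " / ",
         plane(scanDescriptor))
  ids <- tset@manifest$structure_id
  variants <- lapply(tset@patches, generateVariants, config = config)
  H <- nrow(roiImage)

  runPass <- function(indices, bottomUp) {
    prev <- if (bottomUp) Inf else -Inf
    res <- vector("list", nS)
    for (k in indices) {
      m <- if (bottomUp)
        .matchInBand(roiImage, variants[[k]], config, ids[k],
                     direction = "up", maxInterface = prev)
      else
        .matchInBand(roiImage, variants[[k]], config, ids[k],
                     direction = "down", minInterface = prev)
      if (!is.null(m)) {
        res[[k]] <- m$match
        # exclude the accepted band: at least half a window height beyond
        # the peak, further if this template's supra-threshold run reaches
        # deeper — another structure's template can still score above the
        # threshold on this band's near tail
        ir <- .interfaceFromBbox(m$match@bbox)
        rhm <- (roiHeight(m$match@bbox) - 1L) %/% 2L
        prev <- if (bottomUp) min(m$bandEnd, ir - rhm)
                else max(m$bandEnd, ir + rhm)
      }
    }
    res
  }

  topDown <- runPass(seq_len(nS), bottomUp = FALSE)
  bottomUp <- runPass(rev(seq_len(nS)), bottomUp = TRUE)

  preferBottomUp <- config$directionOrder == "bottom_up_first"
  lapply(seq_len(nS), function(k) {
    a <- bottomUp[[k]]; b <- topDown[[k]]
    pick <- if (is.null(a)) b
            else if (is.null(b)) a
            else if (a@score > b@score) a
            else if (b@score > a@score) b
            else if (preferBottomUp) a else b
    if (is.null(pick)) {
      StructureDetection(
        match = MatchResult(structureId = ids[k], score = NA_real_,
                            bbox = NULL, variantIndex = NA_integer_,
                            method = config$method),
        interfaceRow = NA_real_, flag = "detection_failure")
    } else {
      StructureDetection(match = pick,
                         interfaceRow = .interfaceFromBbox(pick@bbox))
    }
  })
}

#' Enforce anatomical ordering on a detection list
#'
#' Detected interfaces must be strictly increasing in depth along the
#' superficial-to-deep template order, and consecutive bounding boxes may
#' not overlap by more than half of the smaller box's height. Each
#' violating pair loses its lower-score member, which is demoted to a
#' flagged failure (`"order_violation"`); the process repeats until the
#' surviving detections are consistent.
#'
#' @param detections list of [StructureDetection-class] in template order
#'   (as returned by [detectStructures()]).
#' @param templates the [TemplateSet-class] used for detection (reserved
#'   for id validation).
#' @return The detection list with violators demoted.
#' @export
validateOrder <- function(detections, templates = NULL) {
  if (!is.null(templates)) {
    known <- templates@manifest$structure_id
    ids <- vapply(detections, structureId, character(1))
    if (!all(ids %in% known))
      stop("detections carry structure ids absent from the template set")
  }
  repeat {
    ok <- which(vapply(detections, function(d) !nzchar(d@flag), logical(1)))
    if (length(ok) < 2L) break
    demote <- NA_integer_
    for (j in seq_len(length(ok) - 1L)) {
      a <- detections[[ok[j]]]; b <- detections[[ok[j + 1L]]]
      deeperOk <- interfaceRow(b) > interfaceRow(a)
      ha <- roiHeight(bbox(a)); hb <- roiHeight(bbox(b))
      ov <- max(0L, min(bbox(a)@bottom, bbox(b)@bottom) -
                    max(bbox(a)@top, bbox(b)@top))
      if (!deeperOk || ov > 0.5 * min(ha, hb)) {
        demote <- if (matchScore(a) <= matchScore(b)) ok[j] else ok[j + 1L]
        break
      }
    }
    if (is.na(demote)) break
    d <- detections[[demote]]
    detections[[demote]] <- StructureDetection(
      match = d@match, contour = d@contour, interfaceRow = d@interfaceRow,
      flag = "order_violation")
  }
  detections
}

#' Binarize a ROI inside a detection's bounding box
#'
#' Thresholds the byte-scale ROI at the Otsu level computed within the
#' bounding box; pixels outside the box are `FALSE`. This is the input
#' [refineContour()] expects.
#'
#' @param roiImage byte-scale numeric matrix.
#' @param box a [ROIBox-class].
#' @return A logical matrix of the same size as `roiImage`.
#' @export
binarizeBbox <- function(roiImage, box) {
  sub <- cropROI(roiImage, box)
  thr <- EBImage::otsu(EBImage::Image(sub / 255), range = c(0, 1),
                       levels = 256L)
  mask <- matrix(FALSE, nrow(roiImage), ncol(roiImage))
  mask[(box@top + 1L):box@bottom, (box@left + 1L):box@right] <- sub / 255 > thr
  mask
}

#' Morphologically refine a detected structure's contour
#'
#' Within the detection's bounding box, applies closing then opening with a
#' disk kernel to the binarized ROI, keeps the largest connected component,
#' traces its boundary, and re-estimates the interface depth as the median
#' row of the component's upper edge (robust to residual speckle). If the
#' mask is empty after morphology the bounding-box outline is used and the
#' detection is flagged `"refine_fallback"`.
#'
#' @param binaryRoi logical matrix from [binarizeBbox()].
#' @param detection a [StructureDetection-class] with a valid bbox.
#' @param kernelRadius disk radius in pixels (default 2, speckle-scale).
#' @return The detection with `contour` and `interfaceRow` updated.
#' @export
refineContour <- function(binaryRoi, detection, kernelRadius = 2L) {
  b <- bbox(detection)
  if (is.null(b)) return(detection)
  sub <- binaryRoi[(b@top + 1L):b@bottom, (b@left + 1L):b@right,
                   drop = FALSE]
  kern <- EBImage::makeBrush(2L * kernelRadius + 1L, shape = "disc")
  m <- EBImage::opening(EBImage::closing(sub * 1, kern), kern)
  lbl <- EBImage::bwlabel(m > 0.5)
  if (max(lbl) == 0) {
    outline <- rbind(
      cbind(b@top, b@left:(b@right - 1L)),
      cbind(b@top:(b@bottom - 1L), b@right - 1L),
      cbind(b@bottom - 1L, (b@right - 1L):b@left),
      cbind((b@bottom - 1L):b@top, b@left))
    return(StructureDetection(match = detection@match,
                              contour = unique(outline),
                              interfaceRow = detection@interfaceRow,
                              flag = "refine_fallback"))
  }
  sizes <- tabulate(lbl[lbl > 0])
  comp <- lbl == which.max(sizes)
  oc <- EBImage::ocontour(EBImage::bwlabel(comp))[[1]]  # 0-based (row, col)
  contour <- cbind(oc[, 1] + b@top, oc[, 2] + b@left)
  colnames(contour) <- c("row", "col")
  upper <- vapply(seq_len(ncol(comp)), function(j) {
    r <- which(comp[, j])
    if (length(r)) r[1] - 1L else NA_integer_
  }, integer(1))
  ir <- stats::median(upper, na.rm = TRUE) + b@top
  StructureDetection(match = detection@match, contour = contour,
                     interfaceRow = ir, flag = detection@flag)
}
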