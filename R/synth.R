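#' @include AllClasses.R
NULL

#' Specification of a synthetic layered-tissue phantom
#'
#' Describes a speckled, horizontally layered B-mode look-alike with known
#' geometry: bright echo bands at the tissue interfaces (each band occupies
#' rows `[row, row + thickness)`), piecewise-constant zone intensities
#' between them, an optional elliptical muscle-belly inclusion
#' (leg-transverse scans), multiplicative log-normal speckle and a black
#' frame emulating the transducer field edge.
#'
#' @slot descriptor scan category ([ScanDescriptor-class]).
#' @slot rows,cols image size in pixels.
#' @slot cmPerPx ground-truth calibration.
#' @slot marginPx width of the black frame.
#' @slot boundaries data.frame with columns `structure_id`, `row` (band top,
#'   0-based image coordinates), `brightness`, `thickness`; strictly
#'   increasing in depth.
#' @slot zoneMeans mean intensity of each inter-band zone (length
#'   `nrow(boundaries) + 1`).
#' @slot inclusion `NULL` or a list `centerRow`, `centerCol`, `a`, `b`,
#'   `theta`, `intensity`.
#' @slot speckleSigma log-scale SD of the multiplicative speckle.
#' @slot seed RNG seed; (spec, seed) fully determines the image.
#'
#' @param descriptor,rows,cols,cmPerPx,marginPx,boundaries,zoneMeans,inclusion,speckleSigma,seed see slots.
#' @return A `PhantomSpec`.
#' @seealso [phantomSpec()] for the convenience constructor with anatomical
#'   defaults.
#' @export PhantomSpec
#' @exportClass PhantomSpec
PhantomSpec <- setClass(
  "PhantomSpec",
  slots = c(descriptor = "ScanDescriptor", rows = "integer",
            cols = "integer", cmPerPx = "numeric", marginPx = "integer",
            boundaries = "data.frame", zoneMeans = "numeric",
            inclusion = "ANY", speckleSigma = "numeric", seed = "integer")
)

setValidity("PhantomSpec", function(object) {
  msg <- NULL
  b <- object@boundaries
  if (!all(c("structure_id", "row", "brightness", "thickness") %in% names(b)))
    msg <- c(msg, "boundaries needs structure_id, row, brightness, thickness")
  else {
    if (is.unsorted(b$row, strictly = TRUE))
      msg <- c(msg, "boundary rows must be strictly increasing in depth")
    lastEnd <- -Inf
    for (i in seq_len(nrow(b))) {
      if (b$row[i] < lastEnd)
        msg <- c(msg, "interface bands must not overlap")
      lastEnd <- b$row[i] + b$thickness[i]
    }
    m <- object@marginPx
    if (nrow(b) && (b$row[1] < m + .BAND_CLEARANCE_PX ||
                    lastEnd > object@rows - m - .BAND_CLEARANCE_PX))
      msg <- c(msg, sprintf(
        "all bands must lie inside the echo field with %d px clearance",
        .BAND_CLEARANCE_PX))
    if (length(object@zoneMeans) != nrow(b) + 1L)
      msg <- c(msg, "zoneMeans must have one entry per inter-band zone")
  }
  if (object@speckleSigma < 0) msg <- c(msg, "speckleSigma must be >= 0")
  if (object@cmPerPx <= 0) msg <- c(msg, "cmPerPx must be > 0")
  inc <- object@inclusion
  if (!is.null(inc)) {
    need <- c("centerRow", "centerCol", "a", "b", "theta", "intensity")
    if (!all(need %in% names(inc)))
      msg <- c(msg, "inclusion needs centerRow, centerCol, a, b, theta, intensity")
    else if (inc$a <= 0 || inc$b <= 0)
      msg <- c(msg, "inclusion semi-axes must be positive")
  }
  if (is.null(msg)) TRUE else msg
})

setMethod("descriptor", "PhantomSpec", function(x) x@descriptor)

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %s / %s, %d x %d px, %d interfaces, speckle %.2f\n",
              region(object@descriptor), plane(object@descriptor),
              object@rows, object@cols, nrow(object@boundaries),
              object@speckleSigma))
})

#' Ground truth of a synthetic phantom
#'
#' @slot descriptor scan category.
#' @slot roi the true echo-field box ([ROIBox-class]).
#' @slot boundaryRows named numeric: true interface depth (band top row,
#'   image coordinates) per structure.
#' @slot values named numeric: the true clinical variables (same names and
#'   units as [measureStructures()] output).
#' @slot units `"cm"`.
#' @slot cmPerPx the generating calibration.
#' @slot inclusion the generating inclusion (or `NULL`).
#'
#' @param descriptor,roi,boundaryRows,values,units,cmPerPx,inclusion see
#'   slots.
#' @return A `PhantomTruth`.
#' @export PhantomTruth
#' @exportClass PhantomTruth
PhantomTruth <- setClass(
  "PhantomTruth",
  slots = c(descriptor = "ScanDescriptor", roi = "ROIBox",
            boundaryRows = "numeric", values = "numeric",
            units = "character", cmPerPx = "numeric", inclusion = "ANY")
)

setValidity("PhantomTruth", function(object) {
  msg <- NULL
  v <- object@values
  if (all(c("Total Subcutaneous Fat", "Superficial Subcutaneous Fat")
          %in% names(v)) &&
      v[["Total Subcutaneous Fat"]] <
      v[["Superficial Subcutaneous Fat"]] - 1e-12)
    msg <- c(msg, "total subcutaneous fat must be >= superficial")
  if (is.null(msg)) TRUE else msg
})

setMethod("descriptor", "PhantomTruth", function(x) x@descriptor)

setMethod("show", "PhantomTruth", function(object) {
  cat(sprintf("PhantomTruth: %s / %s, %d interfaces\n",
              region(object@descriptor), plane(object@descriptor),
              length(object@boundaryRows)))
  for (nm in names(object@values))
    cat(sprintf("  %-32s %.4f\n", nm, object@values[[nm]]))
})

# Scans are assumed to frame the target anatomy inside the echo field: an
# interface band closer than this to the frame could not hold a centred
# template window and is rejected as an invalid phantom configuration.
.BAND_CLEARANCE_PX <- 8L

# default interface layouts, mirroring the acquisition targets: abdominal
# fat layers and the quadriceps (rectus femoris over vastus intermedius)
.defaultBoundaries <- function(region) {
  if (region == "abdomen")
    data.frame(
      structure_id = c("skin", "fascia_superficial", "muscle_wall",
                       "peritoneum", "peritoneal_deep"),
      row = c(50, 110, 170, 210, 260),
      brightness = c(210, 190, 200, 195, 185),
      thickness = 5,
      stringsAsFactors = FALSE)
  else
    data.frame(
      structure_id = c("skin", "rectus_superficial", "rectus_deep",
                       "vastus_deep"),
      row = c(45, 85, 165, 235),
      brightness = c(210, 200, 195, 185),
      thickness = 5,
      stringsAsFactors = FALSE)
}

.defaultZoneMeans <- function(region) {
  if (region == "abdomen") c(70, 50, 55, 75, 45, 35)
  else c(70, 50, 55, 65, 35)
}

#' Build a phantom specification with anatomical defaults
#'
#' Convenience constructor for [PhantomSpec-class]. The default layouts
#' mirror the scanned anatomy: abdominal scans carry five interfaces (skin,
#' the fascia between superficial and deep subcutaneous fat, the muscle
#' wall ending the subcutaneous compartment, the peritoneum, and the deep
#' peritoneal fat boundary); leg scans carry four (skin, the superficial
#' and deep aponeuroses of the rectus femoris, and the deep vastus
#' boundary). Leg-transverse phantoms additionally receive an elliptical
#' muscle-belly inclusion derived to fit the rectus compartment (unless one
#' is given explicitly).
#'
#' @param region,plane scan category.
#' @param rows,cols image size (default 300 x 260 px, a 3.0 x 2.6 cm field
#'   at the default calibration).
#' @param cmPerPx calibration (default 0.01 cm/px).
#' @param marginPx black frame width (default 20 px).
#' @param speckleSigma multiplicative speckle scale (default 0.25).
#' @param seed RNG seed.
#' @param boundaries,zoneMeans,inclusion overrides of the defaults.
#' @return A [PhantomSpec-class].
#' @examples
#' spec <- phantomSpec("leg", "transverse", seed = 7)
#' spec
#' @export
phantomSpec <- function(region, plane, rows = 300L, cols = 260L,
                        cmPerPx = 0.01, marginPx = 20L, speckleSigma = 0.25,
                        seed = 1L, boundaries = NULL, zoneMeans = NULL,
                        inclusion = NULL) {
  desc <- ScanDescriptor(region, plane)
  if (is.null(boundaries)) boundaries <- .defaultBoundaries(region)
  if (is.null(zoneMeans)) zoneMeans <- .defaultZoneMeans(region)
  if (is.null(inclusion) && region == "leg" && plane == "transverse") {
    i2 <- match("rectus_superficial", boundaries$structure_id)
    i3 <- match("rectus_deep", boundaries$structure_id)
    zoneTop <- boundaries$row[i2] + boundaries$thickness[i2]
    zoneBot <- boundaries$row[i3] - 1
    b <- (zoneBot - zoneTop) / 2 - 4
    a <- min(1.7 * b, cols / 2 - marginPx - 10)
    inclusion <- list(centerRow = (zoneTop + zoneBot) / 2,
                      centerCol = cols / 2, a = a, b = b, theta = 0,
                      intensity = 130)
  }
  sp <- new("PhantomSpec", descriptor = desc, rows = as.integer(rows),
            cols = as.integer(cols), cmPerPx = cmPerPx,
            marginPx = as.integer(marginPx), boundaries = boundaries,
            zoneMeans = as.numeric(zoneMeans), inclusion = inclusion,
            speckleSigma = speckleSigma, seed = as.integer(seed))
  validObject(sp)
  sp
}

.phantomTruth <- function(spec) {
  b <- spec@boundaries
  rowOf <- stats::setNames(b$row, b$structure_id)
  cm <- spec@cmPerPx
  m <- spec@marginPx
  roi <- ROIBox(left = m, right = spec@cols - m, top = m,
                bottom = spec@rows - m)
  vals <- numeric(0)
  reg <- region(spec@descriptor); pl <- plane(spec@descriptor)
  if (reg == "abdomen") {
    vals["Superficial Subcutaneous Fat"] <-
      (rowOf["fascia_superficial"] - rowOf["skin"]) * cm
    vals["Total Subcutaneous Fat"] <-
      (rowOf["muscle_wall"] - rowOf["skin"]) * cm
    vals["Peritoneal Fat"] <-
      (rowOf["peritoneal_deep"] - rowOf["peritoneum"]) * cm
  } else {
    wz <- roiWidth(roi) * cm
    if (pl == "longitudinal")
      vals["Subcutaneous Fat"] <- (rowOf["rectus_superficial"] -
                                     rowOf["skin"]) * cm
    yR <- (rowOf["rectus_deep"] - rowOf["rectus_superficial"]) * cm
    yV <- (rowOf["vastus_deep"] - rowOf["rectus_deep"]) * cm
    vals["Y-axis Anterior Rectus"] <- yR
    vals["X-axis Anterior Rectus"] <- wz
    vals["Y-axis Vastus Intermedius"] <- yV
    vals["X-axis Vastus Intermedius"] <- wz
    vals["Anterior Rectus Area"] <-
      if (pl == "transverse" && !is.null(spec@inclusion))
        pi * spec@inclusion$a * spec@inclusion$b * cm^2
      else yR * wz
    vals["Vastus Intermedius Area"] <- yV * wz
  }
  new("PhantomTruth", descriptor = spec@descriptor, roi = roi,
      boundaryRows = rowOf, values = vals, units = "cm", cmPerPx = cm,
      inclusion = spec@inclusion)
}

#' Generate a synthetic speckle phantom with ground truth
#'
#' Renders the phantom described by `spec`: piecewise-constant depth zones,
#' bright interface bands, the optional elliptical inclusion, multiplied by
#' log-normal speckle with unit mean (`exp(N(-sigma^2/2, sigma^2))`),
#' clipped to 0-255, with a black frame. Deterministic for a given
#' (spec, seed); the calling R session's RNG state is left untouched.
#'
#' @param spec a [PhantomSpec-class].
#' @return A list with elements `scan` ([UltrasoundScan-class]) and
#'   `truth` ([PhantomTruth-class]).
#' @examples
#' ph <- generatePhantom(phantomSpec("abdomen", "longitudinal",
#'                                   speckleSigma = 0))
#' ph$truth
#' @export
generatePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  h <- spec@rows; w <- spec@cols; m <- spec@marginPx
  img <- matrix(0, h, w)
  top <- m; bot <- h - m  # 0-based content rows [top, bot)
  left <- m; right <- w - m
  b <- spec@boundaries
  zoneStarts <- c(top, b$row + b$thickness)
  zoneEnds <- c(b$row, bot)
  for (z in seq_along(spec@zoneMeans)) {
    if (zoneEnds[z] > zoneStarts[z])
      img[(zoneStarts[z] + 1L):zoneEnds[z], (left + 1L):right] <-
        spec@zoneMeans[z]
  }
  inc <- spec@inclusion
  if (!is.null(inc)) {
    rr <- matrix((0:(h - 1)) - inc$centerRow, h, w)
    cc <- matrix((0:(w - 1)) - inc$centerCol, h, w, byrow = TRUE)
    ct <- cos(inc$theta); st <- sin(inc$theta)
    u <- cc * ct + rr * st
    v <- -cc * st + rr * ct
    mask <- (u / inc$a)^2 + (v / inc$b)^2 <= 1
    if (top > 0L) mask[seq_len(top), ] <- FALSE
    if (bot < h) mask[(bot + 1L):h, ] <- FALSE
    if (left > 0L) mask[, seq_len(left)] <- FALSE
    if (right < w) mask[, (right + 1L):w] <- FALSE
    img[mask] <- inc$intensity
  }
  for (i in seq_len(nrow(b))) {
    img[(b$row[i] + 1L):(b$row[i] + b$thickness[i]), (left + 1L):right] <-
      b$brightness[i]
  }
  if (spec@speckleSigma > 0) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(spec@seed)
    s <- spec@speckleSigma
    noise <- matrix(exp(stats::rnorm(h * w, mean = -s^2 / 2, sd = s)), h, w)
    img <- img * noise
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else rm(list = ".Random.seed", envir = globalenv())
  }
  img <- round(pmin(pmax(img, 0), 255))
  scan <- UltrasoundScan(pixels = img, pixelSpacingCm = spec@cmPerPx,
                         sourcePath = "", descriptor = spec@descriptor)
  list(scan = scan, truth = .phantomTruth(spec))
}

#' Cut an interface template library out of a phantom
#'
#' One patch per true interface, centred on the interface row at the
#' horizontal middle of the echo field, ordered superficial to deep. The
#' resulting [TemplateSet-class] is directly usable by
#' [detectStructures()] and round-trips through
#' [writeTemplateLibrary()] / [loadTemplateLibrary()].
#'
#' @param scan an [UltrasoundScan-class] (typically a phantom).
#' @param truth the phantom's [PhantomTruth-class].
#' @param patchSize (rows, cols) of each patch; odd numbers keep the
#'   interface centred (default `c(15, 31)`).
#' @return A [TemplateSet-class].
#' @export
extractTemplates <- function(scan, truth, patchSize = c(15L, 31L)) {
  px <- pixels(scan)
  pr <- as.integer(patchSize[1]); pc <- as.integer(patchSize[2])
  rh <- (pr - 1L) %/% 2L; ch <- (pc - 1L) %/% 2L
  roi <- truth@roi
  c0 <- (roi@left + roi@right) %/% 2L
  ids <- names(truth@boundaryRows)
  patches <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    r0 <- as.integer(truth@boundaryRows[k])
    rows <- (r0 - rh):(r0 + rh); cols <- (c0 - ch):(c0 + ch)
    if (min(rows) < roi@top || max(rows) >= roi@bottom ||
        min(cols) < roi@left || max(cols) >= roi@right)
      stop("template placement error: patch for '", ids[k],
           "' crosses the echo-field frame")
    patches[[k]] <- px[rows + 1L, cols + 1L]
  }
  manifest <- data.frame(
    structure_id = ids,
    region = region(truth@descriptor),
    plane = plane(truth@descriptor),
    order_index = seq_along(ids) - 1L,
    filename = sprintf("%s_%s_%s.png", region(truth@descriptor),
                       plane(truth@descriptor), ids),
    stringsAsFactors = FALSE)
  ts <- TemplateSet(manifest = manifest, patches = patches)
  validObject(ts)
  ts
}

#' Generate a cohort of jittered phantoms
#'
#' `n` phantoms drawn around `baseSpec`: interface depths jittered by
#' discrete uniform offsets in `[-depthPx, depthPx]`, zone mean intensities
#' by uniform relative factors in `[1 - zoneMeanFrac, 1 + zoneMeanFrac]`,
#' each phantom with its own derived speckle seed. Draws that violate the
#' spec's validity (band overlap or frame escape) are rejected and redrawn
#' (bounded retries). Fully reproducible from `seed`.
#'
#' @param n number of phantoms.
#' @param baseSpec the [PhantomSpec-class] to jitter around.
#' @param depthPx maximum absolute depth jitter per interface (default 10).
#' @param zoneMeanFrac maximum relative zone-intensity jitter (default 0.1).
#' @param seed cohort seed.
#' @return A list of `n` elements, each a list with `scan`, `truth`,
#'   `spec`.
#' @export
generateCohort <- function(n, baseSpec, depthPx = 10L, zoneMeanFrac = 0.1,
                           seed = 1L) {
  stopifnot(n >= 1L, is(baseSpec, "PhantomSpec"))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- NULL
    for (try in 1:100) {
      brows <- baseSpec@boundaries$row +
        sample.int(2L * depthPx + 1L, nrow(baseSpec@boundaries),
                   replace = TRUE) - depthPx - 1L
      zm <- baseSpec@zoneMeans *
        stats::runif(length(baseSpec@zoneMeans), 1 - zoneMeanFrac,
                     1 + zoneMeanFrac)
      bnd <- baseSpec@boundaries
      bnd$row <- brows
      sp <- tryCatch(
        phantomSpec(region(baseSpec@descriptor), plane(baseSpec@descriptor),
                    rows = baseSpec@rows, cols = baseSpec@cols,
                    cmPerPx = baseSpec@cmPerPx,
                    marginPx = baseSpec@marginPx,
                    speckleSigma = baseSpec@speckleSigma,
                    seed = sample.int(.Machine$integer.max - 1L, 1L),
                    boundaries = bnd, zoneMeans = zm),
        error = function(e) NULL)
      if (!is.null(sp)) break
    }
    if (is.null(sp))
      stop("could not draw a valid phantom spec after 100 attempts")
    ph <- generatePhantom(sp)
    out[[i]] <- list(scan = ph$scan, truth = ph$truth, spec = sp)
  }
  out
}

#' Tabulate a cohort's ground truth
#'
#' One row per phantom with the true variable values, in the same column
#' layout as [measurementsFrame()] (minus texture and provenance).
#'
#' @param cohort list from [generateCohort()].
#' @param ids image ids (default `phantom_001` ...).
#' @return A data.frame.
#' @export
truthFrame <- function(cohort, ids = sprintf("phantom_%03d",
                                             seq_along(cohort))) {
  records <- lapply(seq_along(cohort), function(i) {
    tr <- cohort[[i]]$truth
    MeasurementRecord(imageId = ids[i], descriptor = tr@descriptor,
                      values = tr@values, units = tr@units)
  })
  measurementsFrame(records)
}

#' Simulate an expert reader on ground-truth values
#'
#' Stands in for the manual reference operator: each true value is
#' perturbed by independent Normal reading noise of standard deviation
#' `sigma` (same units as the values). With `sigma = 0` the reader returns
#' the truth.
#'
#' @param truthDf data.frame from [truthFrame()].
#' @param sigma reader noise SD.
#' @param seed RNG seed.
#' @return The data.frame with noisy measurement columns.
#' @export
simulateReader <- function(truthDf, sigma = 0.05, seed = 1L) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  out <- truthDf
  for (v in intersect(names(out), .ALL_VARIABLES)) {
    ok <- !is.na(out[[v]])
    out[[v]][ok] <- out[[v]][ok] + stats::rnorm(sum(ok), 0, sigma)
  }
  out
}

#' Write a cohort to disk as a batch input directory
#'
#' Emits one grayscale PNG per phantom, named with the scan-type code
#' (`phantom_###_<AB|LEG>_<L|T>.png`), plus `truth.csv` with the true
#' variable values.
#'
#' @param cohort list from [generateCohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- character(length(cohort))
  for (i in seq_along(cohort)) {
    d <- descriptor(cohort[[i]]$scan)
    code <- paste0(if (region(d) == "abdomen") "AB" else "LEG", "_",
                   if (plane(d) == "longitudinal") "L" else "T")
    ids[i] <- sprintf("phantom_%03d_%s", i, code)
    png::writePNG(pixels(cohort[[i]]$scan) / 255,
                  file.path(dir, paste0(ids[i], ".png")))
  }
  tf <- truthFrame(cohort, ids = ids)
  utils::write.csv(tf, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}
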