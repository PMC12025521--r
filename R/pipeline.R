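#' @include AllClasses.R
NULL

.LOG_LEVELS <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)

.log <- function(config, level, fmt, ...) {
  if (.LOG_LEVELS[[level]] >= .LOG_LEVELS[[config$logLevel]])
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
  invisible(NULL)
}

#' Pipeline configuration
#'
#' Bundles every tunable of the per-image pipeline. All parameters carry
#' the package defaults; a JSON config file with the same keys is accepted
#' by the command-line front end.
#'
#' @param templates a [TemplateSet-class] or the path of a template library
#'   directory ([loadTemplateLibrary()]).
#' @param roi a [roiParams()] list.
#' @param filter a [filterParams()] list.
#' @param match a [matchConfig()] list.
#' @param glcm a [glcmSpec()] list.
#' @param cmPerPx fallback calibration (cm/px) for scans without metadata
#'   spacing; `NA` leaves such scans in pixel units.
#' @param kernelRadius morphology disk radius for contour refinement.
#' @param logLevel `"debug"`, `"info"`, `"warn"` or `"quiet"`.
#' @param seed seed propagated to any stochastic utilities (the pipeline
#'   itself is deterministic).
#' @return A list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(templates, roi = roiParams(),
                           filter = filterParams(), match = matchConfig(),
                           glcm = glcmSpec(), cmPerPx = NA_real_,
                           kernelRadius = 2L, logLevel = "warn",
                           seed = 1L) {
  if (is.character(templates)) templates <- loadTemplateLibrary(templates)
  stopifnot(is(templates, "TemplateSet"),
            logLevel %in% names(.LOG_LEVELS))
  structure(list(templates = templates, roi = roi, filter = filter,
                 match = match, glcm = glcm, cmPerPx = cmPerPx,
                 kernelRadius = as.integer(kernelRadius),
                 logLevel = logLevel, seed = as.integer(seed)),
            class = "pipelineConfig")
}

.scanCalibration <- function(scan, config) {
  if (!is.na(pixelSpacing(scan)))
    calibration(pixelSpacing(scan), "dicom")
  else if (!is.na(config$cmPerPx))
    calibration(config$cmPerPx, "config")
  else calibration()
}

#' Run the measurement pipeline on one scan
#'
#' Executes the stages in order: scan-code parsing, grayscale reading, ROI
#' detection on the raw intensities, bilateral filtering, byte rescaling,
#' bidirectional template matching, anatomical-order validation,
#' morphological contour refinement, length/area measurement, and texture
#' feature extraction. A failure in a stage after reading yields a flagged
#' (possibly empty) record carrying the stage name — never a crash — so
#' batch runs are isolated at image granularity; only read errors
#' propagate.
#'
#' @param image path to an image file or an [UltrasoundScan-class].
#' @param config a [pipelineConfig()] list.
#' @param imageId record identifier; defaults to the file stem.
#' @return A [MeasurementRecord-class].
#' @export
runPipeline <- function(image, config, imageId = NULL) {
  if (is.character(image)) {
    if (is.null(imageId))
      imageId <- tools::file_path_sans_ext(basename(image))
    scan <- readScan(image)  # read/format errors abort the image
  } else {
    stopifnot(is(image, "UltrasoundScan"))
    scan <- image
    if (is.null(imageId)) imageId <- "scan"
  }

  fail <- function(stage, e, desc = NULL) {
    .log(config, "warn", "%s stage=%s error: %s", imageId, stage,
         conditionMessage(e))
    MeasurementRecord(imageId = imageId, descriptor = desc,
                      units = "px",
                      provenance = list(failed_stage = stage,
                                        error = conditionMessage(e)),
                      flags = paste0("failed_stage:", stage))
  }

  desc <- descriptor(scan)
  if (is.null(desc))
    return(fail("parse", simpleError(
      "no scan-type code: cannot select templates or variables")))

  roi <- tryCatch(computeROI(pixels(scan), config$roi),
                  error = function(e) e)
  if (inherits(roi, "error")) return(fail("roi", roi, desc))

  prep <- tryCatch({
    raw <- cropROI(pixels(scan), roi)
    filt <- bilateralFilter(raw / 255, config$filter)
    rescaleToByte(filt)
  }, error = function(e) e)
  if (inherits(prep, "error")) return(fail("filter", prep, desc))

  detections <- tryCatch({
    d <- detectStructures(prep, config$templates, desc, config$match)
    d <- validateOrder(d, config$templates)
    lapply(d, function(x) {
      if (is.null(bbox(x)) || nzchar(detectionFlag(x))) return(x)
      refineContour(binarizeBbox(prep, bbox(x)), x, config$kernelRadius)
    })
  }, error = function(e) e)
  if (inherits(detections, "error")) return(fail("detect", detections, desc))
  for (d in detections)
    if (nzchar(detectionFlag(d)))
      .log(config, "info", "%s stage=detect structure=%s flag=%s", imageId,
           structureId(d), detectionFlag(d))

  cal <- .scanCalibration(scan, config)
  record <- tryCatch(
    measureStructures(detections, roi, desc, cal, roiImage = prep,
                      imageId = imageId),
    error = function(e) e)
  if (inherits(record, "error")) return(fail("measure", record, desc))

  texture <- tryCatch(textureVariables(prep, config$glcm),
                      error = function(e) e)
  if (inherits(texture, "error")) {
    .log(config, "warn", "%s stage=features error: %s", imageId,
         conditionMessage(texture))
    record@flags <- c(record@flags, "failed_stage:features")
  } else {
    record@texture <- texture
  }
  record@provenance$roi <- as.list(roiCoords(roi))
  record@provenance$interface_rows_image <- stats::setNames(
    vapply(detections, interfaceRow, numeric(1)) + roi@top,
    vapply(detections, structureId, character(1)))
  validObject(record)
  record
}

#' Run the pipeline over a directory of scans
#'
#' Processes every supported image in `inputDir` in sorted-path order
#' (deterministic), isolating failures per image, and writes one
#' measurements CSV (plus its JSON provenance sidecar). Rerunning on the
#' same inputs and configuration produces a byte-identical CSV.
#'
#' @param inputDir directory containing the scans.
#' @param config a [pipelineConfig()] list.
#' @param outCsv output CSV path (default `measurements.csv` inside
#'   `inputDir`).
#' @return A list with `report` (counts and per-image status), `records`,
#'   and `csv` (the output path). The report's `allFailed` field is the
#'   recommended process exit criterion.
#' @export
runBatch <- function(inputDir, config,
                     outCsv = file.path(inputDir, "measurements.csv")) {
  if (!dir.exists(inputDir)) stop("input directory not found: ", inputDir)
  files <- sort(list.files(inputDir, full.names = TRUE,
    pattern = paste0("\\.(", paste(.SUPPORTED_EXT, collapse = "|"),
                     ")$"), ignore.case = TRUE))
  if (length(files) == 0L)
    stop("no supported images (", paste(.SUPPORTED_EXT, collapse = ", "),
         ") in ", inputDir)
  status <- character(length(files))
  stage <- character(length(files))
  records <- vector("list", length(files))
  for (i in seq_along(files)) {
    rec <- tryCatch(runPipeline(files[i], config),
                    error = function(e) e)
    if (inherits(rec, "error")) {
      .log(config, "warn", "%s stage=read error: %s", basename(files[i]),
           conditionMessage(rec))
      status[i] <- "failed"; stage[i] <- "read"
      next
    }
    records[[i]] <- rec
    fs <- grep("^failed_stage:", rec@flags, value = TRUE)
    if (length(fs)) {
      status[i] <- "failed"; stage[i] <- sub("^failed_stage:", "", fs[1])
    } else if (length(rec@flags)) {
      status[i] <- "flagged"; stage[i] <- ""
    } else {
      status[i] <- "succeeded"; stage[i] <- ""
    }
  }
  keep <- !vapply(records, is.null, logical(1))
  if (any(keep)) writeMeasurements(records[keep], outCsv)
  report <- list(
    total = length(files),
    succeeded = sum(status == "succeeded"),
    flagged = sum(status == "flagged"),
    failed = sum(status == "failed"),
    allFailed = all(status == "failed"),
    images = data.frame(file = basename(files), status = status,
                        failure_stage = stage, stringsAsFactors = FALSE))
  .log(config, "info", "batch: %d total, %d succeeded, %d flagged, %d failed",
       report$total, report$succeeded, report$flagged, report$failed)
  list(report = report, records = records[keep],
       csv = if (any(keep)) outCsv else NA_character_)
}

#' Agreement report between automatic and manual measurement stores
#'
#' Joins two measurement CSVs on `image_id`, and per shared length/area
#' variable computes the precision score (100 minus the mean absolute
#' percentage error) and the Bland-Altman statistics. Unmatched ids and
#' variables are skipped with a log entry.
#'
#' @param autoCsv,manualCsv CSV paths ([writeMeasurements()] /
#'   [readMeasurements()] layout; the manual store needs at least
#'   `image_id` plus variable columns).
#' @param outDir if non-`NULL`, writes `agreement_summary.csv` and one
#'   `bland_altman_<variable>.csv` of plot points per variable.
#' @param logLevel logging threshold.
#' @return A data.frame with one row per variable: `variable`, `n`,
#'   `precision_pct`, `bias`, `loa_low`, `loa_high`.
#' @export
runAgreement <- function(autoCsv, manualCsv, outDir = NULL,
                         logLevel = "warn") {
  config <- list(logLevel = logLevel)
  auto <- readMeasurements(autoCsv)
  manual <- readMeasurements(manualCsv)
  shared <- intersect(auto$image_id, manual$image_id)
  if (length(shared) == 0L)
    stop("no overlapping image ids between ", autoCsv, " and ", manualCsv)
  skipped <- setdiff(union(auto$image_id, manual$image_id), shared)
  if (length(skipped))
    .log(config, "info", "skipping %d unmatched image ids", length(skipped))
  a <- auto[match(shared, auto$image_id), , drop = FALSE]
  m <- manual[match(shared, manual$image_id), , drop = FALSE]
  vars <- intersect(intersect(names(a), names(m)), .ALL_VARIABLES)
  rows <- list()
  plots <- list()
  for (v in vars) {
    ok <- !is.na(a[[v]]) & !is.na(m[[v]]) & m[[v]] != 0
    if (sum(ok) < 2L) {
      .log(config, "info", "variable '%s': fewer than 2 usable pairs", v)
      next
    }
    ba <- blandAltman(a[[v]][ok], m[[v]][ok], variable = v)
    rows[[v]] <- data.frame(
      variable = v, n = ba@n,
      precision_pct = precisionPercent(a[[v]][ok], m[[v]][ok]),
      bias = ba@bias, loa_low = ba@loaLow, loa_high = ba@loaHigh,
      stringsAsFactors = FALSE)
    plots[[v]] <- cbind(image_id = shared[ok], ba@points)
  }
  if (length(rows) == 0L) stop("no variable had 2 or more usable pairs")
  summary <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(summary, file.path(outDir, "agreement_summary.csv"),
                     row.names = FALSE)
    for (v in names(plots)) {
      safe <- gsub("[^A-Za-z0-9]+", "_", tolower(v))
      utils::write.csv(plots[[v]],
                       file.path(outDir, paste0("bland_altman_", safe,
                                                ".csv")),
                       row.names = FALSE)
    }
  }
  summary
}
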