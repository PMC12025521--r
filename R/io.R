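#' @include AllClasses.R
NULL

.SUPPORTED_EXT <- c("png", "jpg", "jpeg", "bmp", "dcm")

# canonical column order for the length/area variables
.ALL_VARIABLES <- c(
  "Total Subcutaneous Fat", "Superficial Subcutaneous Fat", "Peritoneal Fat",
  "Subcutaneous Fat",
  "Y-axis Anterior Rectus", "X-axis Anterior Rectus", "Anterior Rectus Area",
  "Y-axis Vastus Intermedius", "X-axis Vastus Intermedius",
  "Vastus Intermedius Area")

.TEXTURE_VARIABLES <- c("asm", "contrast", "correlation", "dissimilarity",
                        "entropy", "histogram_mean", "homogeneity")

#' Read an ultrasound image
#'
#' Reads a 2-D B-mode scan from any of the four supported formats (`png`,
#' `jpg`/`jpeg`, `bmp`, `dcm`), converts colour input to grayscale with the
#' standard luma weights (see [toGrayscale()]), and parses the scan-type code
#' from the file name when possible. For DICOM input the pixel spacing is
#' taken from the file's metadata (PixelSpacing, mm, converted to cm) and
#' MONOCHROME1 data are inverted so higher values always mean brighter
#' echoes.
#'
#' @param path path to the image file.
#' @param pixelSpacingOverride optional cm-per-pixel calibration; takes
#'   precedence over any metadata value.
#' @param scanDescriptor optional [ScanDescriptor-class]; when `NULL` the
#'   descriptor is parsed from the file name with [parseScanCode()] (left
#'   `NULL` if the name carries no recognizable code).
#' @return An [UltrasoundScan-class] with intensities in 0-255.
#' @examples
#' f <- tempfile(fileext = ".png")
#' png::writePNG(matrix(17 / 255, 64, 64), f)
#' s <- readScan(f)
#' range(pixels(s))  # 17 17
#' @export
readScan <- function(path, pixelSpacingOverride = NA_real_,
                     scanDescriptor = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (!(ext %in% .SUPPORTED_EXT))
    stop("unsupported image format '", ext, "'; expected one of: ",
         paste(.SUPPORTED_EXT, collapse = ", "))
  spacing <- NA_real_
  px <- switch(ext,
    png = round(.dropAlpha(png::readPNG(path)) * 255),
    jpg = ,
    jpeg = round(.dropAlpha(jpeg::readJPEG(path)) * 255),
    bmp = .readBMP(path),
    dcm = {
      d <- .readDICOM(path)
      spacing <- d$pixelSpacingCm
      d$pixels
    })
  if (!is.na(pixelSpacingOverride)) spacing <- pixelSpacingOverride
  gray <- toGrayscale(px)
  storage.mode(gray) <- "double"  # identical representation across formats
  if (is.null(scanDescriptor))
    scanDescriptor <- tryCatch(parseScanCode(basename(path)),
                               error = function(e) NULL)
  UltrasoundScan(pixels = gray, pixelSpacingCm = spacing,
                 sourcePath = as.character(path),
                 descriptor = scanDescriptor)
}

.dropAlpha <- function(x) {
  if (length(dim(x)) == 3L && dim(x)[3] >= 3L) x[, , 1:3, drop = FALSE]
  else if (length(dim(x)) == 3L && dim(x)[3] == 2L) x[, , 1L]  # gray + alpha
  else x
}

#' Parse the scan-type code from a file name
#'
#' Scans are annotated with a code in the file name following the grammar
#' `<anything>_<AB|LEG>_<L|T>.<ext>` (case-insensitive): `AB` = abdomen,
#' `LEG` = leg/thigh, `L` = longitudinal, `T` = transverse. A custom mapping
#' table can replace the default grammar for sites using other notations.
#'
#' @param name file name (directories and extension are ignored).
#' @param mapping optional data.frame with columns `code`, `region`, `plane`;
#'   when given, the file stem must end in `_<code>` for one of its rows.
#' @return A [ScanDescriptor-class].
#' @examples
#' parseScanCode("P001_AB_L.png")    # abdomen / longitudinal
#' parseScanCode("P001_LEG_T.dcm")   # leg / transverse
#' @export
parseScanCode <- function(name, mapping = NULL) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("name must be a single non-empty string")
  stem <- tools::file_path_sans_ext(basename(name))
  if (!is.null(mapping)) {
    stopifnot(all(c("code", "region", "plane") %in% names(mapping)))
    for (i in seq_len(nrow(mapping))) {
      if (grepl(paste0("_", mapping$code[i], "$"), stem, ignore.case = TRUE))
        return(ScanDescriptor(mapping$region[i], mapping$plane[i],
                              code = mapping$code[i]))
    }
    stop("unrecognized scan code in '", name, "'; valid codes: ",
         paste(mapping$code, collapse = ", "))
  }
  m <- regmatches(stem, regexec("_(AB|LEG)_(L|T)$", stem, ignore.case = TRUE))[[1]]
  if (length(m) != 3L)
    stop("unrecognized scan code in '", name,
         "'; expected '<anything>_<AB|LEG>_<L|T>.<ext>' ",
         "(AB = abdomen, LEG = leg, L = longitudinal, T = transverse)")
  region <- if (toupper(m[2]) == "AB") "abdomen" else "leg"
  plane  <- if (toupper(m[3]) == "L") "longitudinal" else "transverse"
  ScanDescriptor(region, plane, code = paste0(m[2], "_", m[3]))
}

#' Load a template library from disk
#'
#' A template library is a directory of grayscale PNG patches plus a
#' `manifest.tsv` with columns `structure_id`, `region`, `plane`,
#' `order_index` and `filename`. `order_index` encodes the
#' superficial-to-deep anatomical ordering within each scan category.
#'
#' @param root directory containing `manifest.tsv` and the patch files.
#' @param maxPatchPx maximum allowed patch side length in pixels; larger
#'   patches are a load error (they could not slide inside a conformant
#'   scan).
#' @return A [TemplateSet-class].
#' @seealso [writeTemplateLibrary()], [extractTemplates()]
#' @export
loadTemplateLibrary <- function(root, maxPatchPx = 128L) {
  manifestPath <- file.path(root, "manifest.tsv")
  if (!dir.exists(root)) stop("template library directory not found: ", root)
  if (!file.exists(manifestPath))
    stop("template library manifest missing: ", manifestPath)
  manifest <- utils::read.delim(manifestPath, stringsAsFactors = FALSE)
  need <- c("structure_id", "region", "plane", "order_index", "filename")
  if (!all(need %in% names(manifest)))
    stop("manifest.tsv must have columns: ", paste(need, collapse = ", "))
  if (nrow(manifest) == 0L) stop("template library is empty: ", root)
  patches <- lapply(manifest$filename, function(f) {
    p <- file.path(root, f)
    if (!file.exists(p)) stop("template patch missing: ", p)
    patch <- round(.dropAlpha(png::readPNG(p)) * 255)
    patch <- toGrayscale(patch)
    if (nrow(patch) > maxPatchPx || ncol(patch) > maxPatchPx)
      stop("template patch ", f, " exceeds the maximum size of ",
           maxPatchPx, " px")
    patch
  })
  ts <- TemplateSet(manifest = manifest, patches = patches)
  validObject(ts)
  ts
}

#' Write a template library to disk
#'
#' Inverse of [loadTemplateLibrary()]: one grayscale PNG per patch plus the
#' `manifest.tsv`.
#'
#' @param templates a [TemplateSet-class].
#' @param root output directory (created if needed).
#' @return `root`, invisibly.
#' @export
writeTemplateLibrary <- function(templates, root) {
  stopifnot(is(templates, "TemplateSet"))
  dir.create(root, showWarnings = FALSE, recursive = TRUE)
  m <- templates@manifest
  for (i in seq_len(nrow(m))) {
    png::writePNG(templates@patches[[i]] / 255, file.path(root, m$filename[i]))
  }
  utils::write.table(m, file.path(root, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(root)
}

#' Convert measurement records to a data.frame
#'
#' One row per record; the length/area columns are the union of the
#' variables present across the records (in canonical order), followed by
#' the seven texture columns; variables not measured for a scan are `NA`.
#'
#' @param records list of [MeasurementRecord-class] objects.
#' @return A data.frame.
#' @export
measurementsFrame <- function(records) {
  stopifnot(length(records) > 0L)
  present <- unique(unlist(lapply(records, function(r) names(r@values))))
  vars <- c(intersect(.ALL_VARIABLES, present),
            sort(setdiff(present, .ALL_VARIABLES)))
  rows <- lapply(records, function(r) {
    d <- r@descriptor
    base <- data.frame(
      image_id = r@imageId,
      region = if (is.null(d)) NA_character_ else region(d),
      plane = if (is.null(d)) NA_character_ else plane(d),
      units = r@units,
      stringsAsFactors = FALSE, check.names = FALSE)
    for (v in vars) base[[v]] <- unname(r@values[v])
    for (tv in .TEXTURE_VARIABLES)
      base[[tv]] <- if (tv %in% names(r@texture)) unname(r@texture[[tv]])
                    else NA_real_
    base$flags <- paste(r@flags, collapse = ";")
    base
  })
  do.call(rbind, rows)
}

#' Write measurement records to a CSV store
#'
#' Persists records as a UTF-8 CSV (header row, `.` decimal separator) with
#' a JSON sidecar (`<path>.json`) holding per-record provenance: template
#' ids, match scores, area approximations and processing flags. Numeric
#' values are written at full precision and round-trip losslessly through
#' [readMeasurements()].
#'
#' @param records non-empty list of [MeasurementRecord-class] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeMeasurements <- function(records, path) {
  if (length(records) == 0L) stop("no measurement records to write")
  if (is(records, "MeasurementRecord")) records <- list(records)
  df <- measurementsFrame(records)
  out <- df
  num <- vapply(out, is.numeric, logical(1))
  for (j in which(num))
    out[[j]] <- ifelse(is.na(df[[j]]), "", sprintf("%.17g", df[[j]]))
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) stop("cannot write measurements to '", path, "': ",
                              conditionMessage(e)))
  sidecar <- lapply(records, function(r)
    c(list(image_id = r@imageId, flags = r@flags), r@provenance))
  names(sidecar) <- vapply(records, function(r) r@imageId, character(1))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a measurement CSV written by [writeMeasurements()]
#'
#' @param path CSV path.
#' @return A data.frame with one row per record (full numeric precision).
#' @export
readMeasurements <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  for (j in seq_along(df)) {
    if (names(df)[j] %in% c("image_id", "region", "plane", "units", "flags"))
      next
    df[[j]] <- as.numeric(df[[j]])
  }
  df
}
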