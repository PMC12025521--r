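## Lightweight DICOM support: single-frame, uncompressed, 8-bit grayscale,
## little-endian (explicit or implicit VR) Part-10 files. Pixel spacing is
## taken from PixelSpacing (0028,0030), stored in mm per the standard and
## converted to cm; MONOCHROME1 photometric interpretation is inverted so
## that higher values always mean brighter echoes.

.dcmU16 <- function(raw, i) sum(as.integer(raw[i + 0:1]) * c(1, 256))
.dcmU32 <- function(raw, i) sum(as.integer(raw[i + 0:3]) * 256^(0:3))

# VRs that use the long (2 reserved + 4-byte length) explicit form
.DCM_LONG_VR <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

# string value, with trailing null/space padding dropped (nul bytes cannot
# pass through rawToChar)
.dcmRawToStr <- function(v) trimws(rawToChar(v[v != as.raw(0L)]))

.readDICOM <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 140L || rawToChar(raw[129:132]) != "DICM")
    stop("not a Part-10 DICOM file: ", path)
  pos <- 133L  # first byte after the DICM magic (1-based)
  n <- length(raw)

  elems <- list()
  explicit <- TRUE       # file meta group is always explicit little endian
  metaDone <- FALSE
  transferSyntax <- "1.2.840.10008.1.2.1"

  readElement <- function() {
    group <- .dcmU16(raw, pos)
    elem  <- .dcmU16(raw, pos + 2L)
    hdr <- 8L
    if (explicit || group == 0x0002) {
      vr <- rawToChar(raw[pos + 4:5])
      if (vr %in% .DCM_LONG_VR) {
        len <- .dcmU32(raw, pos + 8L)
        hdr <- 12L
      } else {
        len <- .dcmU16(raw, pos + 6L)
      }
    } else {
      vr <- "UN"
      len <- .dcmU32(raw, pos + 4L)
    }
    if (len == 4294967295) stop("undefined-length DICOM elements not supported")
    list(group = group, elem = elem, vr = vr, len = len,
         valueStart = pos + hdr, nextPos = pos + hdr + len)
  }

  while (pos + 7L <= n) {
    e <- readElement()
    if (!metaDone && e$group != 0x0002) {
      metaDone <- TRUE
      explicit <- transferSyntax != "1.2.840.10008.1.2"
      next  # re-parse this element with the dataset's VR mode
    }
    val <- raw[seq.int(e$valueStart, length.out = e$len)]
    tag <- sprintf("%04x,%04x", e$group, e$elem)
    if (tag == "0002,0010")
      transferSyntax <- .dcmRawToStr(val)
    elems[[tag]] <- list(vr = e$vr, value = val)
    pos <- e$nextPos
    if (tag == "7fe0,0010") break
  }

  getStr <- function(tag) {
    v <- elems[[tag]]
    if (is.null(v)) return(NA_character_)
    .dcmRawToStr(v$value)
  }
  getU16 <- function(tag) {
    v <- elems[[tag]]
    if (is.null(v)) return(NA_integer_)
    .dcmU16(v$value, 1L)
  }

  rows <- getU16("0028,0010")
  cols <- getU16("0028,0011")
  bits <- getU16("0028,0100")
  if (is.na(rows) || is.na(cols)) stop("DICOM file lacks Rows/Columns: ", path)
  if (!is.na(bits) && bits != 8L)
    stop("only 8-bit DICOM pixel data is supported (got ", bits, " bits)")
  pd <- elems[["7fe0,0010"]]
  if (is.null(pd)) stop("DICOM file lacks pixel data: ", path)
  if (length(pd$value) < rows * cols)
    stop("truncated DICOM pixel data in ", path)
  px <- matrix(as.integer(pd$value[seq_len(rows * cols)]),
               nrow = rows, ncol = cols, byrow = TRUE)

  photometric <- getStr("0028,0004")
  if (identical(photometric, "MONOCHROME1")) px <- 255L - px

  spacingCm <- NA_real_
  sp <- getStr("0028,0030")
  if (!is.na(sp) && nzchar(sp)) {
    mm <- suppressWarnings(as.numeric(strsplit(sp, "\\\\")[[1]]))
    if (length(mm) && all(is.finite(mm)) && all(mm > 0))
      spacingCm <- mm[1] / 10
  }

  list(pixels = px, pixelSpacingCm = spacingCm)
}

# Minimal writer (explicit VR little endian); only what the reader and the
# format round-trip tests need.
.writeDICOM <- function(pixels, path, pixelSpacingCm = NA_real_,
                        photometric = "MONOCHROME2") {
  stopifnot(is.matrix(pixels))
  px <- round(pixels)
  if (any(px < 0 | px > 255)) stop("DICOM writer expects intensities in 0..255")
  con <- file(path, "wb")
  on.exit(close(con))

  evenPad <- function(s, padByte = 0x20) {  # 0x00 pads UIDs, space pads text
    v <- charToRaw(s)
    if (length(v) %% 2L) c(v, as.raw(padByte)) else v
  }
  wTagShort <- function(group, elem, vr, value) {
    writeBin(as.integer(c(group, elem)), con, size = 2, endian = "little")
    writeBin(charToRaw(vr), con)
    writeBin(as.integer(length(value)), con, size = 2, endian = "little")
    writeBin(value, con)
  }
  wTagLong <- function(group, elem, vr, value) {
    writeBin(as.integer(c(group, elem)), con, size = 2, endian = "little")
    writeBin(charToRaw(vr), con)
    writeBin(as.integer(0L), con, size = 2, endian = "little")
    writeBin(as.integer(length(value)), con, size = 4, endian = "little")
    writeBin(value, con)
  }
  u16raw <- function(x) as.raw(c(x %% 256L, x %/% 256L))

  writeBin(as.raw(rep(0L, 128L)), con)
  writeBin(charToRaw("DICM"), con)
  # file meta group: just the transfer syntax (explicit LE)
  ts <- evenPad("1.2.840.10008.1.2.1", 0x00)
  # group length of the meta elements that follow
  metaLen <- 8L + length(ts)
  wTagShort(0x0002, 0x0000, "UL",
            as.raw(c(metaLen %% 256L, (metaLen %/% 256L) %% 256L, 0L, 0L)))
  wTagShort(0x0002, 0x0010, "UI", ts)

  wTagShort(0x0028, 0x0004, "CS", evenPad(photometric))
  wTagShort(0x0028, 0x0010, "US", u16raw(nrow(px)))
  wTagShort(0x0028, 0x0011, "US", u16raw(ncol(px)))
  wTagShort(0x0028, 0x0100, "US", u16raw(8L))
  if (!is.na(pixelSpacingCm)) {
    mm <- format(pixelSpacingCm * 10, digits = 10)
    wTagShort(0x0028, 0x0030, "DS",
              evenPad(paste(mm, mm, sep = "\\")))
  }
  vals <- as.integer(t(px))  # row-major pixel order
  if (length(vals) %% 2L) vals <- c(vals, 0L)
  wTagLong(0x7FE0, 0x0010, "OB", as.raw(vals))
  invisible(path)
}
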