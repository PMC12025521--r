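## Lightweight BMP support: uncompressed BITMAPINFOHEADER files, 8-bit
## palettized or 24-bit BGR — the flavours ultrasound consoles export.

.readBMP <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 54L || rawToChar(raw[1:2]) != "BM")
    stop("not a BMP file: ", path)
  u16 <- function(i) sum(as.integer(raw[i + 0:1]) * c(1, 256))
  u32 <- function(i) sum(as.integer(raw[i + 0:3]) * 256^(0:3))
  dataOffset <- u32(11L)
  headerSize <- u32(15L)
  if (headerSize < 40L) stop("unsupported BMP header in ", path)
  width  <- u32(19L)
  height <- u32(23L)
  bottomUp <- TRUE
  if (height > 2^31 - 1) stop("unsupported BMP height")
  bpp <- u16(29L)
  compression <- u32(31L)
  if (compression != 0L)
    stop("compressed BMP not supported: ", path)
  if (!(bpp %in% c(8L, 24L)))
    stop("unsupported BMP bit depth (", bpp, "); expected 8 or 24")

  if (bpp == 8L) {
    nPal <- u32(47L)
    if (nPal == 0L) nPal <- 256L
    palStart <- 14L + headerSize
    pal <- matrix(as.integer(raw[palStart + seq_len(nPal * 4L)]),
                  ncol = 4L, byrow = TRUE)  # B, G, R, reserved
    rowBytes <- ((width + 3L) %/% 4L) * 4L
    px <- matrix(0L, height, width)
    for (r in seq_len(height)) {
      off <- dataOffset + (r - 1L) * rowBytes
      px[height - r + 1L, ] <- as.integer(raw[off + seq_len(width)])
    }
    # palettized: resolve through the palette; grayscale palettes give a
    # single channel, colour palettes a 3-channel array
    b <- matrix(pal[px + 1L, 1L], nrow(px), ncol(px))
    g <- matrix(pal[px + 1L, 2L], nrow(px), ncol(px))
    r <- matrix(pal[px + 1L, 3L], nrow(px), ncol(px))
    if (all(b == g) && all(g == r)) return(r)
    out <- array(0, c(height, width, 3L))
    out[, , 1] <- r; out[, , 2] <- g; out[, , 3] <- b
    return(out)
  }

  rowBytes <- ((width * 3L + 3L) %/% 4L) * 4L
  out <- array(0, c(height, width, 3L))
  cols3 <- seq_len(width * 3L)
  for (r in seq_len(height)) {
    off <- dataOffset + (r - 1L) * rowBytes
    v <- as.integer(raw[off + cols3])
    tr <- height - r + 1L
    out[tr, , 3] <- v[seq(1L, by = 3L, length.out = width)]  # B
    out[tr, , 2] <- v[seq(2L, by = 3L, length.out = width)]  # G
    out[tr, , 1] <- v[seq(3L, by = 3L, length.out = width)]  # R
  }
  out
}

# 8-bit grayscale writer with an identity palette (used for round-trips and
# by the phantom cohort exporter when BMP output is requested)
.writeBMP <- function(pixels, path) {
  stopifnot(is.matrix(pixels))
  px <- round(pixels)
  if (any(px < 0 | px > 255)) stop("BMP writer expects intensities in 0..255")
  h <- nrow(px); w <- ncol(px)
  rowBytes <- ((w + 3L) %/% 4L) * 4L
  dataOffset <- 14L + 40L + 256L * 4L
  fileSize <- dataOffset + rowBytes * h
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("BM"), con)
  writeBin(as.integer(c(fileSize, 0L, dataOffset)), con, size = 4,
           endian = "little")
  writeBin(as.integer(c(40L, w, h)), con, size = 4, endian = "little")
  writeBin(as.integer(c(1L, 8L)), con, size = 2, endian = "little")
  writeBin(as.integer(c(0L, rowBytes * h, 2835L, 2835L, 256L, 0L)), con,
           size = 4, endian = "little")
  pal <- as.raw(rep(0:255, each = 4L) * c(1L, 1L, 1L, 0L))
  writeBin(pal, con)
  pad <- as.raw(rep(0L, rowBytes - w))
  for (r in seq(h, 1L)) {  # bottom-up row order
    writeBin(as.raw(px[r, ]), con)
    if (length(pad)) writeBin(pad, con)
  }
  invisible(path)
}
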