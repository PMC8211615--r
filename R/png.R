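# Tiny PNG codec: 8-bit RGB, filter type 0, zlib stream via memCompress.
# Only what the renderer needs; kept in-package so rendered views can be
# exported without an external graphics dependency.

u32be <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %/% 16777216, x %/% 65536, x %/% 256, x) %% 256)
}

png_chunk <- function(type, data = raw()) {
  body <- c(charToRaw(type), data)
  c(u32be(length(data)), body, u32be(cpp_crc32(body)))
}

#' Write an RGB image as PNG
#'
#' @param img numeric array `height x width x 3` with values in `[0, 1]`
#'   (clamped), or an integer array in `[0, 255]`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_png <- function(img, path) {
  if (length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("img must be height x width x 3")
  h <- dim(img)[1]; w <- dim(img)[2]
  if (is.double(img)) img <- round(pmin(pmax(img, 0), 1) * 255)
  img <- array(as.integer(img), dim(img))
  # scanlines: filter byte 0, then RGB triples left to right, top to bottom
  px <- aperm(img, c(3, 2, 1))                # [channel, col, row]
  m <- rbind(0L, matrix(px, nrow = 3L * w))   # prepend filter byte per row
  payload <- as.raw(m)
  ihdr <- c(u32be(w), u32be(h), as.raw(c(8L, 2L, 0L, 0L, 0L)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)), con)
  writeBin(png_chunk("IHDR", ihdr), con)
  writeBin(png_chunk("IDAT", memCompress(payload, "gzip")), con)
  writeBin(png_chunk("IEND"), con)
  invisible(path)
}

#' Read a PNG written by [write_png()]
#'
#' Supports the subset this package emits (8-bit RGB, filter 0); used for
#' round-trip testing and for analysing rendered views.
#'
#' @param path PNG file.
#' @return integer array `height x width x 3` in `[0, 255]`.
#' @export
read_png <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (!identical(as.integer(raw[1:8]), c(137L, 80L, 78L, 71L, 13L, 10L, 26L, 10L)))
    stop("not a PNG file")
  pos <- 9L
  idat <- raw(0)
  w <- h <- NULL
  while (pos <= length(raw)) {
    len <- sum(as.integer(raw[pos:(pos + 3)]) * c(16777216, 65536, 256, 1))
    type <- rawToChar(raw[(pos + 4):(pos + 7)])
    data <- if (len > 0) raw[(pos + 8):(pos + 7 + len)] else raw(0)
    if (type == "IHDR") {
      w <- sum(as.integer(data[1:4]) * c(16777216, 65536, 256, 1))
      h <- sum(as.integer(data[5:8]) * c(16777216, 65536, 256, 1))
      if (as.integer(data[9]) != 8L || as.integer(data[10]) != 2L)
        stop("only 8-bit RGB PNG supported")
    } else if (type == "IDAT") {
      idat <- c(idat, data)
    } else if (type == "IEND") break
    pos <- pos + 12L + len
  }
  payload <- memDecompress(idat, "gzip")
  m <- matrix(as.integer(payload), nrow = 3L * w + 1L)
  if (any(m[1, ] != 0L)) stop("unsupported PNG filter type")
  px <- array(m[-1, , drop = FALSE], c(3L, w, h))
  aperm(px, c(3, 2, 1))
}
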