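# Minimal 16-bit grayscale PNG writer.
#
# The png package decodes 16-bit grayscale but only encodes 8-bit, so the
# 16-bit path emits the stream by hand: IHDR / IDAT / IEND with the zlib
# payload as stored (uncompressed) DEFLATE blocks. Files are larger than a
# compressed PNG but byte-valid; png::readPNG serves as the independent
# decoder in the tests.

u32be <- function(v) {
  v <- as.numeric(v)
  as.raw(c(v %/% 16777216, (v %/% 65536) %% 256, (v %/% 256) %% 256, v %% 256))
}

crc32_raw <- function(bytes) {
  hex <- digest::digest(bytes, algo = "crc32", serialize = FALSE)
  hex <- formatC(hex, width = 8, flag = "0")
  strtoi(substr(hex, 1, 4), 16L) * 65536 + strtoi(substr(hex, 5, 8), 16L)
}

adler32 <- function(bytes) {
  s1 <- 1; s2 <- 0
  v <- as.integer(bytes)
  # chunked so the double-precision partial sums stay exact
  for (start in seq(1L, length(v), by = 5000L)) {
    chunk <- v[start:min(start + 4999L, length(v))]
    cs <- cumsum(chunk)
    s2 <- (s2 + length(chunk) * s1 + sum(cs)) %% 65521
    s1 <- (s1 + cs[length(cs)]) %% 65521
  }
  s2 * 65536 + s1
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(u32be(length(data)), body, u32be(crc32_raw(body)))
}

# Stored-block DEFLATE wrap of `data` inside a zlib stream.
zlib_stored <- function(data) {
  n <- length(data)
  starts <- seq(1L, max(n, 1L), by = 65535L)
  blocks <- lapply(seq_along(starts), function(i) {
    s <- starts[i]; e <- min(s + 65534L, n)
    len <- if (n == 0L) 0L else e - s + 1L
    hdr <- as.raw(if (i == length(starts)) 1L else 0L)
    c(hdr, writeBin(c(len, bitwXor(len, 65535L)), raw(), size = 2L, endian = "little"),
      if (len > 0L) data[s:e] else raw(0L))
  })
  c(as.raw(c(0x78, 0x01)), do.call(c, blocks), u32be(adler32(data)))
}

write_png16 <- function(pixels, path) {
  stopifnot(is.matrix(pixels), all(pixels >= 0), all(pixels <= 65535))
  h <- nrow(pixels); w <- ncol(pixels)
  v <- as.numeric(t(pixels))                    # row-major sample order
  sample_bytes <- as.raw(rbind(v %/% 256, v %% 256))   # big-endian pairs
  dim(sample_bytes) <- c(2L * w, h)
  scanlines <- rbind(matrix(as.raw(0L), 1L, h), sample_bytes)  # filter byte 0
  data <- as.vector(scanlines)
  ihdr <- c(u32be(w), u32be(h), as.raw(c(16L, 0L, 0L, 0L, 0L)))
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", zlib_stored(data)),
           png_chunk("IEND", raw(0L)))
  writeBin(out, path)
  invisible(path)
}
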