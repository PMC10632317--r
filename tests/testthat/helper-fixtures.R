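# Fixtures are built in code at test time; nothing binary ships with the
# package.

rand_img <- function(h = 64, w = h, seed = 1) {
  withr::with_seed(seed, matrix(runif(h * w), h, w))
}

# vertical step edge: left-half columns `lo`, right-half columns `hi`
step_img <- function(n = 16, lo = 0.3, hi = 0.7) {
  matrix(rep(c(rep(lo, n / 2), rep(hi, n / 2)), each = n), n, n)
}

full_mask <- function(h, w = h) xmpipe:::new_lung_mask(matrix(TRUE, h, w))

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# outlier-tail image: 99% of mass spread over [0.4, 0.6], 1% at 1.0
outlier_img <- function(seed = 1) {
  v <- c(seq(0.4, 0.6, length.out = 9900), rep(1, 100))
  withr::with_seed(seed, matrix(v[sample(10000)], 100, 100))
}

# hand-built DICOM stream (optionally broken) for parser error tests
make_dicom_file <- function(path, pixels = matrix(0L, 32, 32),
                            include_pixeldata = TRUE, n_frames = NULL) {
  e <- xmpipe:::dcm_element
  s <- xmpipe:::dcm_str_element
  u16 <- xmpipe:::dcm_uint16
  body <- c(
    e(0x0028L, 0x0002L, "US", u16(1L)),
    s(0x0028L, 0x0004L, "CS", "MONOCHROME2"),
    if (!is.null(n_frames)) s(0x0028L, 0x0008L, "IS", as.character(n_frames)),
    e(0x0028L, 0x0010L, "US", u16(nrow(pixels))),
    e(0x0028L, 0x0011L, "US", u16(ncol(pixels))),
    e(0x0028L, 0x0100L, "US", u16(16L)),
    e(0x0028L, 0x0101L, "US", u16(12L)),
    e(0x0028L, 0x0103L, "US", u16(0L)),
    if (include_pixeldata) e(0x7FE0L, 0x0010L, "OW", u16(as.integer(t(pixels))))
  )
  meta <- s(0x0002L, 0x0010L, "UI", "1.2.840.10008.1.2.1")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, body), con)
  path
}
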