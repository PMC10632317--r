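# Image ingest and export.
#
# The common currency of the package is the "normalized image": a plain
# numeric matrix on [0,1] in display orientation (mediastinum/bone bright,
# aerated lung dark). MONOCHROME1 sources are inverted on ingest so both
# photometric conventions land in the same representation; display
# window/level metadata is never applied.

#' Construct a raw x-ray image
#'
#' Container for stored pixel values straight off disk, before
#' normalization. Rarely called directly; [read_image()] returns one.
#'
#' @param pixels 2-D integer matrix of stored values.
#' @param bit_depth bits of stored range (e.g. 8, 12, 16).
#' @param photometric `"MONO1"` (low stored value renders bright) or
#'   `"MONO2"`.
#' @param source_format `"DICOM"` or `"PNG"`.
#' @return object of class `xray_raw`.
#' @export
raw_image <- function(pixels, bit_depth, photometric = c("MONO2", "MONO1"),
                      source_format = c("DICOM", "PNG")) {
  photometric <- match.arg(photometric)
  source_format <- match.arg(source_format)
  check_that(is.matrix(pixels) && length(dim(pixels)) == 2L,
             "pixels must be a 2-D matrix")
  check_that(nrow(pixels) >= 32 && ncol(pixels) >= 32,
             "image too small: both dimensions must be >= 32")
  check_that(is_count(bit_depth) && bit_depth <= 16, "bit_depth must be in 1..16")
  check_that(all(is.finite(pixels)), "pixels must be finite")
  check_that(all(pixels >= 0) && all(pixels <= 2^bit_depth - 1),
             "pixel values outside [0, 2^bit_depth - 1]")
  structure(list(pixels = pixels, bit_depth = as.integer(bit_depth),
                 photometric = photometric, source_format = source_format),
            class = "xray_raw")
}

#' @export
print.xray_raw <- function(x, ...) {
  cat(sprintf("<xray_raw> %dx%d, %d-bit, %s, from %s\n", nrow(x$pixels),
              ncol(x$pixels), x$bit_depth, x$photometric, x$source_format))
  invisible(x)
}

# light-weight contract check used at every operator entry point
check_norm_image <- function(img, what = "img") {
  check_that(is.matrix(img) && is.numeric(img), "%s must be a numeric matrix", what)
  check_that(all(is.finite(img)), "%s contains NaN/Inf", what)
  check_that(min(img) >= 0 && max(img) <= 1, "%s has values outside [0,1]", what)
  invisible(img)
}

sniff_format <- function(path) {
  n <- file.info(path)$size
  head <- readBin(path, "raw", n = min(n, 132L))
  if (length(head) >= 8L &&
      identical(head[1:8], as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)))) {
    return("PNG")
  }
  if (length(head) >= 132L && rawToChar(head[129:132]) == "DICM") return("DICOM")
  # headerless DICOM datasets are legal; fall back on the extension
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("dcm", "dicom", "")) return("DICOM")
  if (ext == "png") return("PNG")
  stopf("format error: cannot identify '%s' as DICOM or PNG", path)
}

#' Read an x-ray image from DICOM or PNG
#'
#' Returns the raw stored pixel values: DICOM rescale slope/intercept is
#' applied (then re-quantized), but window/level is ignored, matching a
#' pipeline that consumes raw detector data rather than display renderings.
#' PNG files are assumed MONO2 (larger = brighter) since PNG carries no
#' photometric tag.
#'
#' @param path path to a single-frame grayscale DICOM or an 8/16-bit
#'   grayscale PNG.
#' @return an [raw_image()] object.
#' @export
read_image <- function(path) {
  check_that(file.exists(path), "file not found: '%s'", path)
  fmt <- sniff_format(path)
  if (fmt == "DICOM") {
    d <- read_dicom(path)
    raw_image(d$pixels, d$bit_depth, photometric = d$photometric,
              source_format = "DICOM")
  } else {
    arr <- png::readPNG(path, info = TRUE)
    info <- attr(arr, "info")
    if (length(dim(arr)) == 3L) {
      stopf("unsupported input: PNG with %d channels (grayscale required)",
            dim(arr)[3])
    }
    bits <- info$bit.depth
    if (!bits %in% c(8L, 16L)) stopf("unsupported input: %d-bit PNG", bits)
    pixels <- matrix(as.integer(round(arr * (2^bits - 1))), nrow(arr), ncol(arr))
    raw_image(pixels, bits, photometric = "MONO2", source_format = "PNG")
  }
}

#' Normalize a raw image to the canonical [0,1] representation
#'
#' Divides by the full stored range `2^bit_depth - 1` (no histogram
#' adjustment here) and inverts MONO1 sources so all images share one
#' orientation convention.
#'
#' @param img an [raw_image()] object.
#' @return numeric matrix on `[0,1]`.
#' @export
to_normalized <- function(img) {
  check_that(inherits(img, "xray_raw"), "img must be an xray_raw object")
  v <- img$pixels / (2^img$bit_depth - 1)
  if (img$photometric == "MONO1") v <- 1 - v
  check_norm_image(v)
}

#' Write a normalized image to PNG or DICOM
#'
#' Re-quantizes to the requested bit depth by rounding; reading the file
#' back and normalizing recovers the input within `1/(2^bit_depth - 1)`.
#' The format is chosen by extension: `.png` or `.dcm`/`.dicom`.
#'
#' @param img numeric matrix on `[0,1]`.
#' @param path output path.
#' @param bit_depth 8 or 16.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, bit_depth = 16L) {
  check_norm_image(img)
  check_that(bit_depth %in% c(8L, 16L), "bit_depth must be 8 or 16")
  q <- round(img * (2^bit_depth - 1))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (bit_depth == 8L) {
      png::writePNG(q / 255, path)
    } else {
      write_png16(q, path)
    }
  } else if (ext %in% c("dcm", "dicom")) {
    write_dicom(q, path, bits_stored = bit_depth)
  } else {
    stopf("cannot infer output format from extension '.%s' (use .png or .dcm)", ext)
  }
  invisible(path)
}

#' Read a dataset manifest
#'
#' @param path CSV with columns `path` (image file) and `label` (0/1).
#' @return data.frame with character `path` and integer `label`.
#' @export
read_manifest <- function(path) {
  check_that(file.exists(path), "file not found: '%s'", path)
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  check_that(all(c("path", "label") %in% names(df)),
             "manifest must have columns 'path' and 'label'")
  check_that(all(df$label %in% c(0L, 1L)), "labels must be 0 or 1")
  df$label <- as.integer(df$label)
  df
}

#' @rdname read_manifest
#' @param df data.frame with columns `path`, `label`.
#' @export
write_manifest <- function(df, path) {
  check_that(all(c("path", "label") %in% names(df)),
             "manifest must have columns 'path' and 'label'")
  write.csv(df[, c("path", "label")], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
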