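# Minimal single-frame grayscale DICOM I/O.
#
# Scope: uncompressed little-endian transfer syntaxes only (explicit VR
# "1.2.840.10008.1.2.1" written; explicit or implicit VR read), one frame,
# one sample per pixel, MONOCHROME1/2. Anything else is rejected rather than
# silently converted. Rescale slope/intercept are honoured on read; display
# window/level (VOI LUT) tags are deliberately ignored so the stored "raw"
# pixel values reach the pipeline untouched.

UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
UID_IMPLICIT_LE <- "1.2.840.10008.1.2"
UID_SC_STORAGE <- "1.2.840.10008.5.1.4.1.1.7"

# VRs carrying a 2-byte reserved field and 4-byte length in explicit mode
LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

dcm_uint16 <- function(v) {
  v <- as.integer(v)
  writeBin(ifelse(v > 32767L, v - 65536L, v), raw(), size = 2L, endian = "little")
}

dcm_element <- function(group, element, vr, value_raw) {
  if (length(value_raw) %% 2L == 1L) {
    pad <- if (vr %in% c("UI", "OB")) as.raw(0L) else charToRaw(" ")
    value_raw <- c(value_raw, pad)
  }
  head <- c(dcm_uint16(group), dcm_uint16(element), charToRaw(vr))
  if (vr %in% LONG_VRS) {
    c(head, raw(2L), writeBin(length(value_raw), raw(), size = 4L, endian = "little"),
      value_raw)
  } else {
    c(head, dcm_uint16(length(value_raw)), value_raw)
  }
}

dcm_str_element <- function(group, element, vr, text) {
  dcm_element(group, element, vr, charToRaw(text))
}

#' Write a single-frame grayscale DICOM file
#'
#' Emits an uncompressed explicit-VR little-endian file with the minimal
#' image-pixel module. Used both as the package's DICOM output path and to
#' build test fixtures programmatically.
#'
#' @param pixels integer matrix of stored values in `[0, 2^bits_stored - 1]`.
#' @param path output file path.
#' @param bits_stored stored bit depth (1..16); bits allocated is 8 or 16.
#' @param photometric `"MONOCHROME2"` (default, larger = brighter) or
#'   `"MONOCHROME1"`.
#' @param rescale optional `c(slope, intercept)` written as Rescale tags.
#' @return `path`, invisibly.
#' @export
write_dicom <- function(pixels, path, bits_stored = 12L,
                        photometric = c("MONOCHROME2", "MONOCHROME1"),
                        rescale = NULL) {
  photometric <- match.arg(photometric)
  stopifnot(is.matrix(pixels))
  check_that(is_count(bits_stored) && bits_stored >= 1 && bits_stored <= 16,
             "bits_stored must be in 1..16")
  pixels <- round(pixels)
  check_that(all(pixels >= 0) && all(pixels <= 2^bits_stored - 1),
             "pixel values exceed the stated bit depth")
  bits_alloc <- if (bits_stored <= 8) 8L else 16L

  body <- c(
    dcm_str_element(0x0008L, 0x0016L, "UI", UID_SC_STORAGE),
    dcm_str_element(0x0008L, 0x0018L, "UI", "1.2.826.0.1.3680043.8.498.1"),
    dcm_element(0x0028L, 0x0002L, "US", dcm_uint16(1L)),
    dcm_str_element(0x0028L, 0x0004L, "CS", photometric),
    dcm_element(0x0028L, 0x0010L, "US", dcm_uint16(nrow(pixels))),
    dcm_element(0x0028L, 0x0011L, "US", dcm_uint16(ncol(pixels))),
    dcm_element(0x0028L, 0x0100L, "US", dcm_uint16(bits_alloc)),
    dcm_element(0x0028L, 0x0101L, "US", dcm_uint16(bits_stored)),
    dcm_element(0x0028L, 0x0102L, "US", dcm_uint16(bits_stored - 1L)),
    dcm_element(0x0028L, 0x0103L, "US", dcm_uint16(0L))
  )
  if (!is.null(rescale)) {
    body <- c(body,
              dcm_str_element(0x0028L, 0x1052L, "DS", format(rescale[2])),
              dcm_str_element(0x0028L, 0x1053L, "DS", format(rescale[1])))
  }
  # pixel data, row-major per DICOM convention (rows of the displayed image)
  v <- as.integer(t(pixels))
  pix_raw <- if (bits_alloc == 8L) {
    writeBin(ifelse(v > 127L, v - 256L, v), raw(), size = 1L)
  } else {
    dcm_uint16(v)
  }
  body <- c(body, dcm_element(0x7FE0L, 0x0010L, "OW", pix_raw))

  meta <- c(
    dcm_element(0x0002L, 0x0001L, "OB", as.raw(c(0L, 1L))),
    dcm_str_element(0x0002L, 0x0002L, "UI", UID_SC_STORAGE),
    dcm_str_element(0x0002L, 0x0003L, "UI", "1.2.826.0.1.3680043.8.498.1"),
    dcm_str_element(0x0002L, 0x0010L, "UI", UID_EXPLICIT_LE),
    dcm_str_element(0x0002L, 0x0012L, "UI", "1.2.826.0.1.3680043.8.498.2")
  )
  group_len <- dcm_element(0x0002L, 0x0000L, "UL",
                           writeBin(length(meta), raw(), size = 4L, endian = "little"))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(group_len, meta, body), con)
  invisible(path)
}

# --- reading ----------------------------------------------------------------

rd_uint16 <- function(buf, pos) {
  readBin(buf[pos:(pos + 1L)], "integer", size = 2L, signed = FALSE,
          endian = "little")
}
rd_uint32 <- function(buf, pos) {
  lo <- rd_uint16(buf, pos); hi <- rd_uint16(buf, pos + 2L)
  lo + hi * 65536
}

KNOWN_VRS <- c("AE","AS","AT","CS","DA","DS","DT","FL","FD","IS","LO","LT",
               "OB","OF","OW","PN","SH","SL","SQ","SS","ST","TM","UI","UL",
               "UN","US","UT")

# Parse one data element; returns list(group, element, vr, value raw, next pos)
dcm_next_element <- function(buf, pos, explicit) {
  group <- rd_uint16(buf, pos)
  element <- rd_uint16(buf, pos + 2L)
  pos <- pos + 4L
  if (explicit) {
    vr <- rawToChar(buf[pos:(pos + 1L)])
    if (!vr %in% KNOWN_VRS) stopf("DICOM parse error: unknown VR '%s'", vr)
    if (vr %in% LONG_VRS) {
      len <- rd_uint32(buf, pos + 4L); pos <- pos + 8L
    } else {
      len <- rd_uint16(buf, pos + 2L); pos <- pos + 4L
    }
  } else {
    vr <- NA_character_
    len <- rd_uint32(buf, pos); pos <- pos + 4L
  }
  if (len == 4294967295) {
    stopf("DICOM parse error: undefined-length element (%04x,%04x) unsupported",
          group, element)
  }
  if (pos + len - 1L > length(buf)) stopf("DICOM parse error: truncated element")
  value <- if (len > 0) buf[pos:(pos + len - 1L)] else raw(0L)
  list(group = group, element = element, vr = vr, value = value,
       pos = pos + len)
}

dcm_value_str <- function(el) trimws(rawToChar(el$value))
dcm_value_us <- function(el) rd_uint16(el$value, 1L)

#' Read a single-frame grayscale DICOM file
#'
#' Parses explicit or implicit VR little-endian uncompressed files. Rescale
#' slope/intercept are applied and the result re-quantized to integers
#' clipped to `[0, 2^bits_stored - 1]`; window/level tags are ignored.
#'
#' @param path file path.
#' @return list with `pixels` (integer matrix), `bit_depth`, `photometric`.
#' @keywords internal
read_dicom <- function(path) {
  buf <- readBin(path, "raw", n = file.info(path)$size)
  pos <- 1L
  if (length(buf) >= 132L && rawToChar(buf[129:132]) == "DICM") pos <- 133L

  explicit <- TRUE
  transfer <- UID_EXPLICIT_LE
  fields <- list(samples = 1L, frames = 1L, slope = 1, intercept = 0,
                 photometric = "MONOCHROME2")
  pixel_raw <- NULL
  in_meta_probe <- TRUE
  while (pos + 7L <= length(buf)) {
    group <- rd_uint16(buf, pos)
    if (in_meta_probe && group != 0x0002L) {
      # end of file-meta: switch VR mode according to the transfer syntax
      explicit <- !identical(transfer, UID_IMPLICIT_LE)
      if (!transfer %in% c(UID_EXPLICIT_LE, UID_IMPLICIT_LE)) {
        stopf("unsupported transfer syntax '%s' (compressed or big-endian)", transfer)
      }
      in_meta_probe <- FALSE
    }
    el <- dcm_next_element(buf, pos, explicit = if (group == 0x0002L) TRUE else explicit)
    pos <- el$pos
    key <- sprintf("%04x%04x", el$group, el$element)
    if (key == "00020010") transfer <- dcm_value_str(el)
    else if (key == "00280002") fields$samples <- dcm_value_us(el)
    else if (key == "00280004") fields$photometric <- dcm_value_str(el)
    else if (key == "00280008") fields$frames <- as.integer(dcm_value_str(el))
    else if (key == "00280010") fields$rows <- dcm_value_us(el)
    else if (key == "00280011") fields$cols <- dcm_value_us(el)
    else if (key == "00280100") fields$bits_alloc <- dcm_value_us(el)
    else if (key == "00280101") fields$bits_stored <- dcm_value_us(el)
    else if (key == "00280103") fields$pixel_rep <- dcm_value_us(el)
    else if (key == "00281052") fields$intercept <- as.numeric(dcm_value_str(el))
    else if (key == "00281053") fields$slope <- as.numeric(dcm_value_str(el))
    else if (key == "7fe00010") pixel_raw <- el$value
  }

  if (is.null(pixel_raw)) stopf("format error: DICOM file has no pixel data element")
  if (is.null(fields$rows) || is.null(fields$cols) || is.null(fields$bits_alloc)) {
    stopf("format error: DICOM image-pixel module incomplete")
  }
  if (fields$samples != 1L || !grepl("^MONOCHROME", fields$photometric)) {
    stopf("unsupported input: color DICOM (SamplesPerPixel %d, %s)",
          fields$samples, fields$photometric)
  }
  if (!is.na(fields$frames) && fields$frames > 1L) {
    stopf("unsupported input: multi-frame DICOM (%d frames)", fields$frames)
  }
  n <- fields$rows * fields$cols
  signed <- isTRUE(fields$pixel_rep == 1L)
  v <- if (fields$bits_alloc == 8L) {
    readBin(pixel_raw, "integer", n = n, size = 1L, signed = signed)
  } else if (fields$bits_alloc == 16L) {
    readBin(pixel_raw, "integer", n = n, size = 2L, signed = signed,
            endian = "little")
  } else {
    stopf("unsupported input: BitsAllocated %d", fields$bits_alloc)
  }
  if (length(v) < n) stopf("format error: pixel data shorter than Rows*Columns")
  v <- v[seq_len(n)]
  bits <- if (is.null(fields$bits_stored)) fields$bits_alloc else fields$bits_stored
  v <- round(fields$slope * v + fields$intercept)
  v <- pmin(pmax(v, 0), 2^bits - 1)
  pixels <- matrix(as.integer(v), nrow = fields$rows, ncol = fields$cols,
                   byrow = TRUE)
  list(pixels = pixels, bit_depth = as.integer(bits),
       photometric = if (fields$photometric == "MONOCHROME1") "MONO1" else "MONO2")
}
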