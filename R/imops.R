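# Low-level raster primitives on plain numeric matrices.
#
# All operators assume row-major anatomy-agnostic matrices in [0,1] and are
# fully vectorized; nothing here depends on image semantics.

gaussian_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Replicate-edge 1-D convolution along rows of `x` with kernel `k` (odd length).
conv_rows <- function(x, k) {
  r <- (length(k) - 1L) / 2L
  if (r == 0L) return(x * k)
  n <- nrow(x)
  idx <- c(rep(1L, r), seq_len(n), rep(n, r))
  xp <- x[idx, , drop = FALSE]
  out <- matrix(0, n, ncol(x))
  for (i in seq_along(k)) {
    out <- out + k[i] * xp[i:(i + n - 1L), , drop = FALSE]
  }
  out
}

#' Gaussian blur with replicate-edge boundary handling
#'
#' Separable Gaussian filter used by unsharp masking, the sharpness operator
#' and machine profiles. `sigma <= 0` is the identity; a length-2 `sigma`
#' gives per-axis (row, column) standard deviations.
#'
#' @param img numeric matrix in `[0,1]`.
#' @param sigma standard deviation in pixels (scalar or `(row, col)` pair).
#' @return blurred matrix, same shape.
#' @export
gaussian_blur <- function(img, sigma) {
  stopifnot(is.matrix(img))
  sigma <- rep_len(sigma, 2L)
  if (all(sigma <= 0)) return(img)
  out <- img
  if (sigma[1] > 0) out <- conv_rows(out, gaussian_kernel_1d(sigma[1]))
  if (sigma[2] > 0) out <- t(conv_rows(t(out), gaussian_kernel_1d(sigma[2])))
  out
}

#' Bilinear resize
#'
#' Pixel-center aligned bilinear interpolation; the work-horse behind
#' [resize_512()] and the classifier's feature grid. When downscaling, a
#' Gaussian anti-aliasing prefilter with per-axis
#' `sigma = (in/out - 1) / 2` is applied first, so shrinking averages
#' rather than subsamples (without it, per-pixel noise survives any amount
#' of downscaling).
#'
#' @param img numeric matrix.
#' @param out_h,out_w output dimensions (positive integers).
#' @return `out_h x out_w` matrix; values stay inside the input range.
#' @export
resize_image <- function(img, out_h, out_w) {
  stopifnot(is.matrix(img))
  check_that(is_count(out_h) && is_count(out_w), "output size must be positive integers")
  h <- nrow(img); w <- ncol(img)
  if (h == out_h && w == out_w) return(img)
  aa <- c(max((h / out_h - 1) / 2, 0), max((w / out_w - 1) / 2, 0))
  if (any(aa > 0)) img <- gaussian_blur(img, aa)
  src_r <- pmin(pmax((seq_len(out_h) - 0.5) * h / out_h - 0.5, 0), h - 1)
  src_c <- pmin(pmax((seq_len(out_w) - 0.5) * w / out_w - 0.5, 0), w - 1)
  r0 <- pmin(floor(src_r), h - 1); r1 <- pmin(r0 + 1, h - 1)
  c0 <- pmin(floor(src_c), w - 1); c1 <- pmin(c0 + 1, w - 1)
  fr <- src_r - r0; fc <- src_c - c0
  a <- img[r0 + 1, c0 + 1, drop = FALSE]
  b <- img[r0 + 1, c1 + 1, drop = FALSE]
  d <- img[r1 + 1, c0 + 1, drop = FALSE]
  e <- img[r1 + 1, c1 + 1, drop = FALSE]
  wr <- matrix(fr, out_h, out_w)
  wc <- matrix(fc, out_h, out_w, byrow = TRUE)
  a * (1 - wr) * (1 - wc) + b * (1 - wr) * wc + d * wr * (1 - wc) + e * wr * wc
}

# Inverse-mapped rotation about the image center, bilinear, constant fill.
rotate_image <- function(img, degrees, fill = 0) {
  stopifnot(is.matrix(img))
  if (degrees == 0) return(img)
  h <- nrow(img); w <- ncol(img)
  th <- degrees * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  rr <- matrix(seq_len(h), h, w) - cy
  cc <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  # inverse rotation of output coordinates back into the source frame
  sr <- cos(th) * rr - sin(th) * cc + cy
  sc <- sin(th) * rr + cos(th) * cc + cx
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  out <- matrix(fill, h, w)
  val <- function(ri, ci) {
    inside <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
    v <- matrix(fill, h, w)
    v[inside] <- img[cbind(ri[inside], ci[inside])]
    list(v = v, inside = inside)
  }
  p00 <- val(r0, c0); p01 <- val(r0, c0 + 1)
  p10 <- val(r0 + 1, c0); p11 <- val(r0 + 1, c0 + 1)
  out <- p00$v * (1 - fr) * (1 - fc) + p01$v * (1 - fr) * fc +
    p10$v * fr * (1 - fc) + p11$v * fr * fc
  any_inside <- p00$inside | p01$inside | p10$inside | p11$inside
  out[!any_inside] <- fill
  out
}
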