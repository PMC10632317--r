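# Pre-processing operators.
#
# Four methods are compared on equal footing: global histogram equalization
# (HE), contrast-limited adaptive histogram equalization (CLAHE), unsharp
# masking (UM), and the histogram modification at the heart of the
# hardware-robust pipeline (XM): iterative percentile-tail clipping with
# re-stretching to [0,1], followed by anchoring the lower stretch bound at
# the minimum intensity inside the lung field. HE and CLAHE operate on the
# classic 256-level quantization of the float image.

#' Parameters of the iterative histogram modification
#'
#' @param clip_frac per-tail fraction of pixel mass clipped per iteration,
#'   in `(0, 0.05]`.
#' @param tol convergence tolerance on bound movement, in normalized units.
#' @param max_iter maximum number of clip/re-stretch iterations.
#' @param n_bins histogram resolution used for the tail quantiles.
#' @return object of class `hist_mod_params`.
#' @export
hist_mod_params <- function(clip_frac = 0.01, tol = 1 / 1024, max_iter = 20L,
                            n_bins = 1024L) {
  check_that(clip_frac > 0 && clip_frac <= 0.05, "clip_frac must be in (0, 0.05]")
  check_that(tol > 0, "tol must be > 0")
  check_that(is_count(max_iter), "max_iter must be >= 1")
  check_that(is_count(n_bins, 64L), "n_bins must be >= 64")
  structure(list(clip_frac = clip_frac, tol = tol,
                 max_iter = as.integer(max_iter), n_bins = as.integer(n_bins)),
            class = "hist_mod_params")
}

PREPROCESS_METHODS <- c("none", "he", "clahe", "um", "xm")

# 256-level quantization index (1..256) of a [0,1] image
quantize256 <- function(img) pmin(floor(img * 256) + 1L, 256L)

#' Global histogram equalization
#'
#' Maps every pixel through the empirical CDF of its own 256-level
#' histogram. The mapping is monotone non-decreasing, so pixel ranking is
#' preserved; a constant image stays constant.
#'
#' @param img numeric matrix on `[0,1]`.
#' @return equalized matrix on `[0,1]`.
#' @export
hist_equalize <- function(img) {
  check_norm_image(img)
  q <- quantize256(img)
  cdf <- cumsum(tabulate(q, 256L)) / length(img)
  matrix(cdf[q], nrow(img), ncol(img))
}

# per-tile clipped-histogram CDF lookup table (256 entries)
clahe_tile_lut <- function(counts, clip_limit) {
  n <- sum(counts)
  clip <- clip_limit * n / 256
  excess <- sum(pmax(counts - clip, 0))
  counts <- pmin(counts, clip) + excess / 256
  cumsum(counts) / n
}

#' Contrast-limited adaptive histogram equalization
#'
#' Classic tile-based CLAHE: the image is divided into a `tiles` grid, each
#' tile's 256-level histogram is clipped at `clip_limit` times the mean bin
#' height (excess redistributed uniformly), and each pixel is mapped by
#' bilinear interpolation between the CDF lookup tables of the four
#' surrounding tile centers. With a single tile and an unbounded clip limit
#' this reduces exactly to [hist_equalize()].
#'
#' @param img numeric matrix on `[0,1]`.
#' @param clip_limit clip level as a multiple of the mean bin height
#'   (`> 0`; `Inf` disables clipping).
#' @param tiles integer pair `(rows, cols)` of the tile grid.
#' @return matrix on `[0,1]`.
#' @export
clahe <- function(img, clip_limit = 4, tiles = c(8L, 8L)) {
  check_norm_image(img)
  check_that(clip_limit > 0, "clip_limit must be > 0")
  tiles <- as.integer(tiles)
  check_that(length(tiles) == 2L && all(tiles >= 1L), "tiles must be a pair >= (1,1)")
  h <- nrow(img); w <- ncol(img)
  check_that(tiles[1] <= h && tiles[2] <= w, "more tiles than pixels")
  q <- quantize256(img)
  # tile index of each row/col (contiguous blocks of near-equal size)
  tile_r <- pmin(floor((seq_len(h) - 1) * tiles[1] / h) + 1L, tiles[1])
  tile_c <- pmin(floor((seq_len(w) - 1) * tiles[2] / w) + 1L, tiles[2])
  luts <- array(0, c(256L, tiles[1], tiles[2]))
  centers_r <- numeric(tiles[1]); centers_c <- numeric(tiles[2])
  for (ti in seq_len(tiles[1])) centers_r[ti] <- mean(which(tile_r == ti))
  for (tj in seq_len(tiles[2])) centers_c[tj] <- mean(which(tile_c == tj))
  for (ti in seq_len(tiles[1])) {
    for (tj in seq_len(tiles[2])) {
      counts <- tabulate(q[tile_r == ti, tile_c == tj], 256L)
      luts[, ti, tj] <- clahe_tile_lut(counts, clip_limit)
    }
  }
  # interpolation weights between neighbouring tile centers, clamped at edges
  interp_idx <- function(pos, centers) {
    k <- length(centers)
    i0 <- pmin(pmax(findInterval(pos, centers), 1L), max(k - 1L, 1L))
    i1 <- pmin(i0 + 1L, k)
    t <- if (k == 1L) rep(0, length(pos)) else
      pmin(pmax((pos - centers[i0]) / (centers[i1] - centers[i0]), 0), 1)
    t[!is.finite(t)] <- 0
    list(i0 = i0, i1 = i1, t = t)
  }
  ir <- interp_idx(seq_len(h), centers_r)
  ic <- interp_idx(seq_len(w), centers_c)
  Ti0 <- matrix(ir$i0, h, w); Ti1 <- matrix(ir$i1, h, w); Tr <- matrix(ir$t, h, w)
  Tj0 <- matrix(ic$i0, h, w, byrow = TRUE); Tj1 <- matrix(ic$i1, h, w, byrow = TRUE)
  Tc <- matrix(ic$t, h, w, byrow = TRUE)
  at <- function(ti, tj) matrix(luts[cbind(as.vector(q), as.vector(ti), as.vector(tj))], h, w)
  out <- at(Ti0, Tj0) * (1 - Tr) * (1 - Tc) + at(Ti0, Tj1) * (1 - Tr) * Tc +
    at(Ti1, Tj0) * Tr * (1 - Tc) + at(Ti1, Tj1) * Tr * Tc
  clamp01(out)
}

#' Unsharp masking
#'
#' `out = clip(img + amount * (img - blur(img, blur_sigma)), 0, 1)`.
#' Defaults follow the 512-pixel working scale: `blur_sigma = 10` px,
#' `amount = 1`.
#'
#' @param img numeric matrix on `[0,1]`.
#' @param blur_sigma Gaussian sigma of the low-pass, in pixels (`> 0`).
#' @param amount high-frequency gain (`>= 0`; 0 is the identity).
#' @return sharpened matrix on `[0,1]`.
#' @export
unsharp_mask <- function(img, blur_sigma = 10, amount = 1) {
  check_norm_image(img)
  check_that(blur_sigma > 0, "blur_sigma must be > 0")
  check_that(amount >= 0, "amount must be >= 0")
  if (amount == 0) return(img)
  clamp01(img + amount * (img - gaussian_blur(img, blur_sigma)))
}

# histogram-based lower/upper tail quantiles at resolution 1/n_bins
tail_bounds <- function(img, clip_frac, n_bins) {
  counts <- tabulate(pmin(floor(as.vector(img) * n_bins) + 1L, n_bins), n_bins)
  cum <- cumsum(counts) / length(img)
  lo_bin <- which(cum >= clip_frac)[1]
  hi_bin <- which(cum >= 1 - clip_frac)[1]
  c((lo_bin - 1L) / n_bins, hi_bin / n_bins)
}

#' Histogram modification of the hardware-robust pipeline
#'
#' Two stages. (1) Iterative stretch: clip `clip_frac` of the pixel mass in
#' each tail (clamping, so clipped mass piles up at the bounds), re-stretch
#' to `[0,1]`, and repeat until both bounds move less than `tol` or
#' `max_iter` is reached; outlier tails are discarded while the fixed point
#' preserves the inlier interval. (2) Lung anchoring: the lower bound of
#' the final linear stretch is replaced by the minimum intensity inside the
#' lung mask, so the darkest lung pixel maps exactly to 0 and the contrast
#' budget is spent inside the lung field.
#'
#' @param img numeric matrix on `[0,1]`.
#' @param mask a `lung_mask` for `img` (never empty; see [segment_lungs()]).
#' @param params a [hist_mod_params()] object.
#' @return modified matrix on `[0,1]`.
#' @export
xm_histogram_modify <- function(img, mask, params = hist_mod_params()) {
  check_norm_image(img)
  check_that(inherits(mask, "lung_mask"), "mask must be a lung_mask")
  check_that(all(dim(mask$mask) == dim(img)), "mask shape must match image")
  check_that(inherits(params, "hist_mod_params"), "params must be hist_mod_params")
  # track the composed affine map through [lo, hi] on the original scale
  lo <- 0; hi <- 1
  x <- img
  for (iter in seq_len(params$max_iter)) {
    if (hi - lo < 1e-9) break   # (near-)constant image: nothing to stretch
    b <- tail_bounds(x, params$clip_frac, params$n_bins)
    if (b[2] <= b[1]) break
    moved <- max(b[1], 1 - b[2])
    new_lo <- lo + b[1] * (hi - lo)
    new_hi <- lo + b[2] * (hi - lo)
    lo <- new_lo; hi <- new_hi
    x <- clamp01((img - lo) / (hi - lo))
    if (moved < params$tol) break
  }
  lung_min <- min(img[mask$mask])
  lo <- lung_min
  if (hi <= lo) hi <- lo + 1 / params$n_bins
  clamp01((img - lo) / (hi - lo))
}

#' Resize to the 512x512 network input size
#'
#' Bilinear; see [resize_image()].
#'
#' @param img numeric matrix on `[0,1]`.
#' @return 512x512 matrix on `[0,1]`.
#' @export
resize_512 <- function(img) {
  check_norm_image(img)
  clamp01(resize_image(img, 512L, 512L))
}

#' Apply one named pre-processing pipeline stage
#'
#' Fixed order: lung crop, method, resize. `"none"` crops and resizes only;
#' the other methods insert the named operator with module defaults.
#'
#' @param img numeric matrix on `[0,1]`.
#' @param mask a `lung_mask` for `img`; segmented on the fly if `NULL`.
#' @param method one of `"none"`, `"he"`, `"clahe"`, `"um"`, `"xm"`.
#' @param out_size output side length (default 512, the network input).
#' @param margin_frac crop margin passed to [crop_to_lungs()].
#' @return `out_size x out_size` matrix on `[0,1]`.
#' @export
preprocess_dispatch <- function(img, mask = NULL, method = "none",
                                out_size = 512L, margin_frac = 0.05) {
  check_norm_image(img)
  check_that(is.character(method) && length(method) == 1L &&
               method %in% PREPROCESS_METHODS,
             "unknown method '%s' (use one of: %s)", as.character(method)[1],
             paste(PREPROCESS_METHODS, collapse = ", "))
  if (is.null(mask)) mask <- segment_lungs(img)
  cr <- crop_to_lungs(img, mask, margin_frac)
  x <- cr$image
  x <- switch(method,
              none = x,
              he = hist_equalize(x),
              clahe = clahe(x),
              um = unsharp_mask(x, blur_sigma = 10 * min(dim(x)) / 512, amount = 1),
              xm = xm_histogram_modify(x, cr$mask))
  clamp01(resize_image(x, out_size, out_size))
}
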