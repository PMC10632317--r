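# Synthetic chest-phantom generator.
#
# Stylized frontal-chest phantoms: a bright mediastinal band, two dark
# elliptical lung fields with low-amplitude rib banding, an optional lesion
# (a flat-core blob for a nodule, a half-lung haze for consolidation) fully
# inside one lung, plus a ground-truth lung mask and a binary label. The
# phantoms are deliberately not anatomically realistic: the test surface
# needs controllable contrast, sharpness and noise, not anatomy. Machine
# profiles impose the contrast/sharpness/noise differences seen between
# stationary DR, cassette CR and mobile CR acquisition chains.

#' Phantom specification
#'
#' @param size square image side, `>= 64`.
#' @param abnormal logical; insert a lesion.
#' @param lesion_kind `"nodule"` (flat-core blob) or `"consolidation"`
#'   (half-lung haze).
#' @param lesion_contrast added intensity of the lesion, in `(0, 0.5]`.
#' @param seed integer seed; the phantom is deterministic given the spec.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(size = 128L, abnormal = FALSE,
                         lesion_kind = c("nodule", "consolidation"),
                         lesion_contrast = 0.2, seed = 1L) {
  lesion_kind <- match.arg(lesion_kind)
  check_that(is_count(size, 64L), "size must be an integer >= 64")
  check_that(lesion_contrast > 0 && lesion_contrast <= 0.5,
             "lesion_contrast must be in (0, 0.5]")
  structure(list(size = as.integer(size), abnormal = isTRUE(abnormal),
                 lesion_kind = lesion_kind, lesion_contrast = lesion_contrast,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate one chest phantom
#'
#' Deterministic per spec (geometry jitter, rib phase and texture noise all
#' derive from `spec$seed`). An abnormal phantom differs from the matched
#' normal phantom of the same seed only by the lesion.
#'
#' @param spec a [phantom_spec()].
#' @return list: `image` (matrix on `[0,1]`), `mask` (ground-truth
#'   `lung_mask`), `label` (0/1), `lesion` (logical footprint matrix or
#'   `NULL`).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  check_that(inherits(spec, "phantom_spec"), "spec must be a phantom_spec")
  n <- spec$size
  with_seed(spec$seed, {
    jit <- function(lo, hi) runif(1, lo, hi)
    rr <- matrix(seq_len(n) / n, n, n)              # row fraction (top -> bottom)
    cc <- matrix(seq_len(n) / n, n, n, byrow = TRUE)

    base <- 0.52 + jit(-0.03, 0.03) + 0.06 * rr      # soft tissue + gradient
    med_c <- 0.5 + jit(-0.02, 0.02)
    img <- base + 0.28 * exp(-((cc - med_c) / 0.11)^2)       # mediastinum
    img <- img + 0.15 / (1 + exp(-(rr - 0.82) * 30))         # diaphragm shelf

    lung_depth <- 0.33 + jit(-0.02, 0.02)
    cen_r <- 0.47 + jit(-0.02, 0.02)
    ax_r <- 0.27 + jit(-0.015, 0.015)
    ax_c <- 0.145 + jit(-0.01, 0.01)
    lung_off <- 0.21 + jit(-0.01, 0.01)
    d2 <- function(center_c) ((rr - cen_r) / ax_r)^2 + ((cc - center_c) / ax_c)^2
    d2l <- d2(med_c - lung_off); d2r <- d2(med_c + lung_off)
    soft <- function(d) pmin(pmax((1 - d) * 6, 0), 1)        # soft ellipse edge
    mask <- d2l <= 1 | d2r <= 1
    img <- img - lung_depth * pmax(soft(d2l), soft(d2r))

    rib_phase <- jit(0, 2 * pi)
    ribs <- 0.03 * sin(2 * pi * 6.5 * rr + rib_phase)
    img <- img + ribs * mask

    lesion <- NULL
    if (spec$abnormal) {
      side_left <- runif(1) < 0.5
      lcen <- if (side_left) med_c - lung_off else med_c + lung_off
      ld2 <- if (side_left) d2l else d2r
      if (spec$lesion_kind == "nodule") {
        # lesion center inside the ellipse core, radius bounded so the
        # footprint stays strictly inside the lung
        repeat {
          u <- runif(1, -0.5, 0.5); v <- runif(1, -0.5, 0.5)
          if (u^2 + v^2 <= 0.35) break
        }
        cy <- cen_r + u * ax_r; cx <- lcen + v * ax_c
        R <- 0.3 * min(ax_r, ax_c) * n * runif(1, 0.8, 1.2)
        r_px <- sqrt(((rr - cy) * n)^2 + ((cc - cx) * n)^2)
        profile <- exp(-(r_px / R)^4)
        img <- img + spec$lesion_contrast * profile
        lesion <- r_px <= R
      } else {
        # haze over the lower half of one lung
        w <- soft(ld2) * pmin(pmax((rr - cen_r) * 12, 0), 1)
        img <- img + spec$lesion_contrast * w
        lesion <- w >= 0.6
      }
    }

    img <- gaussian_blur(img, 0.007 * n)
    img <- img + matrix(rnorm(n * n, 0, 0.008), n, n)
    list(image = clamp01(img), mask = new_lung_mask(mask),
         label = as.integer(spec$abnormal), lesion = lesion)
  })
}

#' Machine acquisition profile
#'
#' Encodes the contrast (gamma), sharpness (blur), brightness offset and
#' noise signature of an acquisition chain.
#'
#' @param name profile label.
#' @param gamma contrast exponent (`1` = neutral).
#' @param blur_sigma Gaussian blur sigma in pixels (`0` = none).
#' @param noise_sigma additive Gaussian noise sd on `[0,1]` (`0` = none).
#' @param intensity_offset additive brightness shift.
#' @return object of class `machine_profile`.
#' @export
machine_profile <- function(name = "IDENTITY", gamma = 1, blur_sigma = 0,
                            noise_sigma = 0, intensity_offset = 0) {
  check_that(all(is.finite(c(gamma, blur_sigma, noise_sigma, intensity_offset))),
             "profile parameters must be finite")
  check_that(gamma > 0, "gamma must be > 0")
  check_that(blur_sigma >= 0 && noise_sigma >= 0,
             "blur_sigma and noise_sigma must be >= 0")
  structure(list(name = name, gamma = gamma, blur_sigma = blur_sigma,
                 noise_sigma = noise_sigma, intensity_offset = intensity_offset),
            class = "machine_profile")
}

#' Shipped machine profiles
#'
#' `IDENTITY` (exact no-op), `DR_STATIONARY` (gamma 1, no blur, sigma
#' 0.01), `CR` (gamma 1.3, blur 1.5 px, sigma 0.03) and `CR_MOBILE` (gamma
#' 1.3, blur 1.5 px, sigma 0.06), echoing the contrast/sharpness/noise axes
#' separating stationary DR, cassette CR and mobile CR chains.
#'
#' @return named list of [machine_profile()] objects.
#' @export
machine_profiles <- function() {
  list(
    IDENTITY = machine_profile("IDENTITY"),
    DR_STATIONARY = machine_profile("DR_STATIONARY", gamma = 1, blur_sigma = 0,
                                    noise_sigma = 0.01),
    CR = machine_profile("CR", gamma = 1.3, blur_sigma = 1.5, noise_sigma = 0.03),
    CR_MOBILE = machine_profile("CR_MOBILE", gamma = 1.3, blur_sigma = 1.5,
                                noise_sigma = 0.06)
  )
}

#' Apply a machine profile to an image
#'
#' Order: gamma, blur, intensity offset, then noise. Identity parameters
#' are skipped, so the `IDENTITY` profile is an exact identity.
#'
#' @param img numeric matrix on `[0,1]`.
#' @param profile a [machine_profile()].
#' @param seed integer seed for the noise component.
#' @return matrix on `[0,1]`.
#' @export
apply_machine_profile <- function(img, profile, seed = 1L) {
  check_that(inherits(profile, "machine_profile"), "profile must be a machine_profile")
  x <- gamma_contrast(img, profile$gamma)
  if (profile$blur_sigma > 0) x <- clamp01(gaussian_blur(x, profile$blur_sigma))
  if (profile$intensity_offset != 0) x <- clamp01(x + profile$intensity_offset)
  add_gaussian_noise(x, profile$noise_sigma, seed = seed)
}

#' Generate a labelled phantom dataset
#'
#' Exactly `round(n * abnormal_frac)` abnormal phantoms, at seed-determined
#' positions; every image is passed through `profile`. Optionally writes
#' 16-bit PNGs plus a `path,label` manifest CSV.
#'
#' @param n number of phantoms, `>= 2`.
#' @param abnormal_frac abnormal fraction in `(0,1)`; must round to neither
#'   0 nor `n`.
#' @param profile a [machine_profile()] (default `IDENTITY`).
#' @param seed integer seed.
#' @param size,lesion_contrast,lesion_kind forwarded to [phantom_spec()].
#' @param dir optional output directory for PNGs and `manifest.csv`.
#' @return list: `images` (list of matrices), `masks` (list of
#'   `lung_mask`), `labels` (0/1 vector), `manifest` (data.frame; paths are
#'   `NA` unless `dir` is given).
#' @export
generate_dataset <- function(n, abnormal_frac = 0.5,
                             profile = machine_profiles()$IDENTITY, seed = 1L,
                             size = 128L, lesion_contrast = 0.2,
                             lesion_kind = "nodule", dir = NULL) {
  check_that(is_count(n, 2L), "n must be >= 2")
  check_that(abnormal_frac > 0 && abnormal_frac < 1,
             "abnormal_frac must be in (0,1)")
  n_abn <- round(n * abnormal_frac)
  check_that(n_abn >= 1 && n_abn < n,
             "abnormal_frac rounds to an all-normal or all-abnormal dataset")
  plan <- with_seed(seed, list(abn = sample.int(n, n_abn),
                               seeds = sample.int(2^30, n)))
  labels <- integer(n)
  labels[plan$abn] <- 1L
  images <- vector("list", n)
  masks <- vector("list", n)
  for (i in seq_len(n)) {
    ph <- generate_phantom(phantom_spec(size = size, abnormal = labels[i] == 1L,
                                        lesion_kind = lesion_kind,
                                        lesion_contrast = lesion_contrast,
                                        seed = plan$seeds[i]))
    img <- apply_machine_profile(ph$image, profile, seed = plan$seeds[i] + 1L)
    images[[i]] <- img
    masks[[i]] <- ph$mask
  }
  paths <- rep(NA_character_, n)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- file.path(dir, sprintf("phantom_%04d.png", seq_len(n)))
    for (i in seq_len(n)) write_image(images[[i]], paths[i], bit_depth = 16L)
    write_manifest(data.frame(path = basename(paths), label = labels),
                   file.path(dir, "manifest.csv"))
  }
  list(images = images, masks = masks, labels = labels,
       manifest = data.frame(path = paths, label = labels,
                             stringsAsFactors = FALSE))
}
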