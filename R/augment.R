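# Hardware-mimicking augmentation operators.
#
# Three physics-motivated axes: gamma correction (generator voltage /
# contrast), a signed sharpness coefficient s (grid and scatter: s < 0
# blurs, s > 0 sharpens), and additive Gaussian noise (dose, detector and
# electronics). Conventional rotation/flip augmentation is provided for the
# baseline pipelines. Every operator is an exact identity at its identity
# parameter, preserves [0,1], and is deterministic given a seed.

S_MAX <- 12          # sharpness coefficient spanning the stress range
SHARP_REF_SIZE <- 512  # sigma definitions are stated at this image side

#' Perturbation triple (gamma, s, sigma)
#'
#' Parameterizes one draw of the contrast/sharpness/noise augmentation, or
#' one deterministic point of a robustness sweep. The identity element is
#' `(1, 0, 0)`.
#'
#' @param gamma contrast exponent, `> 0`.
#' @param sharp signed sharpness coefficient in `[-12, 12]`.
#' @param noise_sigma Gaussian noise standard deviation on the `[0,1]`
#'   scale, `>= 0`.
#' @return object of class `perturb_spec`.
#' @export
perturb_spec <- function(gamma = 1, sharp = 0, noise_sigma = 0) {
  check_that(is.numeric(gamma) && length(gamma) == 1L && is.finite(gamma) &&
               gamma > 0, "gamma must be > 0")
  check_that(is.numeric(sharp) && length(sharp) == 1L && is.finite(sharp),
             "sharp must be a finite number")
  check_that(is.numeric(noise_sigma) && length(noise_sigma) == 1L &&
               is.finite(noise_sigma) && noise_sigma >= 0,
             "noise_sigma must be >= 0")
  structure(list(gamma = gamma, sharp = sharp, noise_sigma = noise_sigma),
            class = "perturb_spec")
}

#' @export
print.perturb_spec <- function(x, ...) {
  cat(sprintf("<perturb_spec> gamma=%.3g, s=%.3g, sigma=%.3g\n",
              x$gamma, x$sharp, x$noise_sigma))
  invisible(x)
}

#' Training-time augmentation configuration
#'
#' Default ranges are the training draws (narrower than the stress-sweep
#' ranges): gamma in (0.5, 2), s in (-6, 6), sigma in (0, 0.05), rotation
#' in (-15, 15) degrees, flip probability 0.5. Each enabled component is
#' drawn uniformly from its range.
#'
#' @param gamma_range,sharp_range,noise_range,rot_deg_range numeric pairs.
#' @param flip_prob horizontal flip probability in `[0,1]`.
#' @param enabled character vector naming the active operators, a subset of
#'   `c("gamma", "sharp", "noise", "rotate", "flip")`.
#' @return object of class `augment_params`.
#' @export
augment_params <- function(gamma_range = c(0.5, 2), sharp_range = c(-6, 6),
                           noise_range = c(0, 0.05), rot_deg_range = c(-15, 15),
                           flip_prob = 0.5,
                           enabled = c("gamma", "sharp", "noise", "rotate", "flip")) {
  ranges <- list(gamma = gamma_range, sharp = sharp_range, noise = noise_range,
                 rotate = rot_deg_range)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    check_that(length(r) == 2L && r[1] <= r[2], "%s_range must be ordered", nm)
  }
  check_that(is_prob(flip_prob), "flip_prob must be in [0,1]")
  check_that(all(enabled %in% c("gamma", "sharp", "noise", "rotate", "flip")),
             "unknown operator in 'enabled'")
  check_that(noise_range[1] == 0, "noise_range must start at 0")
  ident <- c(gamma = 1, sharp = 0, noise = 0, rotate = 0)
  for (nm in intersect(enabled, names(ident))) {
    r <- ranges[[nm]]
    check_that(ident[[nm]] >= r[1] && ident[[nm]] <= r[2],
               "identity value of '%s' must lie inside its enabled range", nm)
  }
  structure(list(gamma_range = gamma_range, sharp_range = sharp_range,
                 noise_range = noise_range, rot_deg_range = rot_deg_range,
                 flip_prob = flip_prob, enabled = enabled),
            class = "augment_params")
}

#' Gamma (contrast) transform
#'
#' `out = img ^ gamma`, modeling the contrast change from a different
#' generator voltage. `gamma = 1` is the identity.
#'
#' @param img numeric matrix on `[0,1]`.
#' @param gamma exponent, `> 0`.
#' @return matrix on `[0,1]`.
#' @export
gamma_contrast <- function(img, gamma) {
  check_norm_image(img)
  check_that(is.numeric(gamma) && length(gamma) == 1L && is.finite(gamma) &&
               gamma > 0, "gamma must be > 0")
  if (gamma == 1) return(img)
  img^gamma
}

#' Signed sharpness adjustment
#'
#' `s = 0` is the identity. `s < 0` applies a Gaussian blur with
#' `sigma = |s|/4` pixels at the 512 reference scale (so `s = -12` is a
#' sigma-3 blur), emulating scatter/grid loss of sharpness. `s > 0` applies
#' unsharp enhancement with amount `s/12` over a sigma-3 blur. Sigmas are
#' scaled by `min(dim)/512` so the operator is consistent across sizes.
#'
#' @param img numeric matrix on `[0,1]`.
#' @param s signed coefficient in `[-12, 12]`.
#' @return matrix on `[0,1]`.
#' @export
adjust_sharpness <- function(img, s) {
  check_norm_image(img)
  check_that(is.numeric(s) && length(s) == 1L && is.finite(s) &&
               abs(s) <= S_MAX, "s must be in [-%d, %d]", S_MAX, S_MAX)
  if (s == 0) return(img)
  scale <- min(dim(img)) / SHARP_REF_SIZE
  if (s < 0) {
    clamp01(gaussian_blur(img, abs(s) / 4 * scale))
  } else {
    clamp01(img + (s / S_MAX) * (img - gaussian_blur(img, 3 * scale)))
  }
}

#' Additive Gaussian noise
#'
#' i.i.d. `N(0, sigma^2)` per pixel, clipped to `[0,1]`; approximates
#' thermal/electronic detector noise. Identical seeds reproduce identical
#' output; the caller's RNG state is untouched.
#'
#' @param img numeric matrix on `[0,1]`.
#' @param sigma noise standard deviation, `>= 0` (`0` is the identity).
#' @param seed integer seed.
#' @return matrix on `[0,1]`.
#' @export
add_gaussian_noise <- function(img, sigma, seed = 1L) {
  check_norm_image(img)
  check_that(is.numeric(sigma) && length(sigma) == 1L && is.finite(sigma) &&
               sigma >= 0, "sigma must be >= 0")
  if (sigma == 0) return(img)
  noise <- with_seed(seed, rnorm(length(img), 0, sigma))
  clamp01(img + matrix(noise, nrow(img), ncol(img)))
}

#' Rotation and horizontal flip
#'
#' Rotation about the image center (bilinear, constant fill 0, shape
#' preserved), then an optional column mirror.
#'
#' @param img numeric matrix on `[0,1]`.
#' @param degrees rotation angle, `|degrees| <= 45`.
#' @param flip logical; mirror columns.
#' @return matrix on `[0,1]`.
#' @export
rotate_flip <- function(img, degrees = 0, flip = FALSE) {
  check_norm_image(img)
  check_that(abs(degrees) <= 45, "|degrees| must be <= 45")
  out <- rotate_image(img, degrees)
  if (flip) out <- out[, rev(seq_len(ncol(out))), drop = FALSE]
  clamp01(out)
}

#' Draw one training augmentation
#'
#' Uniform draws from the configured ranges for each enabled operator
#' (Bernoulli for the flip); disabled operators return their identity
#' values. Reproducible per seed.
#'
#' @param params an [augment_params()] object.
#' @param rng_seed integer seed.
#' @return list with `spec` (a [perturb_spec()]), `degrees`, `flip`.
#' @export
sample_augmentation <- function(params = augment_params(), rng_seed = 1L) {
  check_that(inherits(params, "augment_params"), "params must be augment_params")
  with_seed(rng_seed, {
    draw <- function(nm, range) {
      if (nm %in% params$enabled) runif(1, range[1], range[2]) else NA_real_
    }
    g <- draw("gamma", params$gamma_range)
    s <- draw("sharp", params$sharp_range)
    z <- draw("noise", params$noise_range)
    d <- draw("rotate", params$rot_deg_range)
    f <- if ("flip" %in% params$enabled) runif(1) < params$flip_prob else FALSE
    list(spec = perturb_spec(gamma = if (is.na(g)) 1 else g,
                             sharp = if (is.na(s)) 0 else s,
                             noise_sigma = if (is.na(z)) 0 else z),
         degrees = if (is.na(d)) 0 else d,
         flip = f)
  })
}

#' Apply a perturbation triple
#'
#' Fixed order gamma, then sharpness, then noise: noise enters last, as
#' detector/electronics noise is added after scene formation. The identity
#' spec `(1, 0, 0)` is an exact identity.
#'
#' @param img numeric matrix on `[0,1]`.
#' @param spec a [perturb_spec()].
#' @param seed integer seed for the noise component.
#' @return matrix on `[0,1]`.
#' @export
apply_perturbation <- function(img, spec, seed = 1L) {
  check_that(inherits(spec, "perturb_spec"), "spec must be a perturb_spec")
  x <- gamma_contrast(img, spec$gamma)
  x <- adjust_sharpness(x, spec$sharp)
  add_gaussian_noise(x, spec$noise_sigma, seed = seed)
}
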