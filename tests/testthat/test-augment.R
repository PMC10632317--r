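test_that("gamma transform matches its closed form and validates input", {
  img <- rand_img(32, seed = 1)
  expect_identical(gamma_contrast(img, 1), img)
  expect_equal(gamma_contrast(matrix(0.25, 32, 32), 2)[1], 0.0625)
  expect_equal(gamma_contrast(matrix(0.25, 32, 32), 0.5)[1], 0.5)
  expect_error(gamma_contrast(img, 0), "gamma")
  expect_error(gamma_contrast(img, -1), "gamma")
})

test_that("sharpness coefficient orders edge gradients", {
  img <- rand_img(32, seed = 2)
  expect_identical(adjust_sharpness(img, 0), img)
  const <- matrix(0.5, 64, 64)
  expect_equal(adjust_sharpness(const, 7), const)
  expect_equal(adjust_sharpness(const, -7), const)
  se <- step_img(64, 0.3, 0.7)
  grad <- function(x) max(abs(diff(t(x))))  # max column-direction gradient
  g_sharp <- grad(adjust_sharpness(se, 12))
  g_id <- grad(se)
  g_blur <- grad(adjust_sharpness(se, -12))
  expect_gte(g_sharp, g_id)
  expect_gt(g_id, g_blur)
  expect_error(adjust_sharpness(img, 13), "s must be")
})

test_that("gaussian noise is calibrated, seeded, and clipped", {
  img <- rand_img(32, seed = 3)
  expect_identical(add_gaussian_noise(img, 0), img)
  const <- matrix(0.5, 512, 512)
  noisy <- add_gaussian_noise(const, 0.1, seed = 11)
  res_sd <- sd(noisy - const)
  expect_gte(res_sd, 0.09)
  expect_lte(res_sd, 0.11)
  expect_identical(noisy, add_gaussian_noise(const, 0.1, seed = 11))
  expect_false(identical(noisy, add_gaussian_noise(const, 0.1, seed = 12)))
  extreme <- add_gaussian_noise(matrix(0.01, 64, 64), 0.3, seed = 1)
  expect_gte(min(extreme), 0)
  expect_lte(max(extreme), 1)
})

test_that("rotation and flip respect their identities", {
  img <- rand_img(48, seed = 4)
  expect_identical(rotate_flip(img, 0, FALSE), img)
  expect_equal(rotate_flip(rotate_flip(img, 0, TRUE), 0, TRUE), img)
  expect_error(rotate_flip(img, 60), "degrees")
})

test_that("rotation interpolation loss is small away from the fill border", {
  ph <- generate_phantom(phantom_spec(size = 128, seed = 5))
  sm <- gaussian_blur(ph$image, 1.5)
  back <- rotate_flip(rotate_flip(sm, 15), -15)
  h <- nrow(sm)
  d <- sqrt(outer((seq_len(h) - h / 2)^2, (seq_len(h) - h / 2)^2, "+"))
  central <- d <= 0.35 * h
  # corners rotate out of frame and return as fill; judged on the interior
  expect_lt(mean(abs(back - sm)[central]), 0.02)
})

test_that("augmentation draws are uniform, seeded, and respect 'enabled'", {
  off <- sample_augmentation(augment_params(enabled = character(0)), rng_seed = 1)
  expect_equal(off$spec, perturb_spec(1, 0, 0))
  expect_equal(off$degrees, 0)
  expect_false(off$flip)

  p <- augment_params()
  draws <- vapply(seq_len(10000), function(i) {
    sample_augmentation(p, rng_seed = i)$spec$gamma
  }, numeric(1))
  expect_gte(min(draws), 0.5)
  expect_lte(max(draws), 2.0)
  expect_lt(abs(mean(draws) - 1.25), 0.02)

  expect_identical(sample_augmentation(p, rng_seed = 99),
                   sample_augmentation(p, rng_seed = 99))
})

test_that("augment_params rejects ranges that exclude the identity", {
  expect_error(augment_params(gamma_range = c(2, 3)), "identity")
  expect_error(augment_params(noise_range = c(0.01, 0.05)), "start at 0")
  expect_error(augment_params(flip_prob = 1.5), "flip_prob")
})

test_that("perturbation composition: identity, degeneracy, and noise ordering", {
  img <- rand_img(64, seed = 6)
  expect_identical(apply_perturbation(img, perturb_spec(1, 0, 0)), img)
  expect_identical(apply_perturbation(img, perturb_spec(gamma = 2)),
                   gamma_contrast(img, 2))
  sds <- vapply(c(0, 0.03, 0.08), function(s) {
    sd(apply_perturbation(img, perturb_spec(noise_sigma = s), seed = 7))
  }, numeric(1))
  expect_true(all(diff(sds) > 0))
})

test_that("perturb_spec validates its invariants", {
  expect_error(perturb_spec(gamma = 0), "gamma")
  expect_error(perturb_spec(noise_sigma = -0.1), "noise_sigma")
})
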