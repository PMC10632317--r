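test_that("histogram equalization maps levels to empirical CDF values", {
  img <- matrix(rep(c(0.25, 0.75), each = 128), 16, 16)
  out <- hist_equalize(img)
  expect_equal(sort(unique(as.vector(out))), c(0.5, 1.0))
  expect_equal(out[img == 0.25][1], 0.5)
  expect_equal(out[img == 0.75][1], 1.0)
})

test_that("histogram equalization is monotone and total on degenerate input", {
  const <- hist_equalize(matrix(0.42, 20, 20))
  expect_equal(length(unique(as.vector(const))), 1L)
  expect_false(anyNA(const))
  img <- rand_img(32, seed = 5)
  out <- hist_equalize(img)
  ord <- order(img)
  expect_true(all(diff(out[ord]) >= 0))
})

test_that("CLAHE degenerates to HE with one tile and unbounded clip", {
  img <- rand_img(64, seed = 6)
  expect_lte(max(abs(clahe(img, clip_limit = Inf, tiles = c(1, 1)) -
                       hist_equalize(img))), 1 / 255)
})

test_that("CLAHE keeps range, handles constants, validates tiles", {
  img <- rand_img(64, seed = 7)
  out <- clahe(img, clip_limit = 2, tiles = c(4, 4))
  expect_gte(min(out), 0)
  expect_lte(max(out), 1)
  const <- clahe(matrix(0.3, 32, 32), clip_limit = 2, tiles = c(2, 2))
  expect_equal(length(unique(as.vector(const))), 1L)
  expect_error(clahe(img, tiles = c(100, 100)), "tiles")
  expect_error(clahe(img, clip_limit = 0), "clip_limit")
})

test_that("unsharp masking sharpens a step edge and respects identities", {
  img <- rand_img(32, seed = 8)
  expect_identical(unsharp_mask(img, blur_sigma = 2, amount = 0), img)
  const <- matrix(0.6, 32, 32)
  expect_equal(unsharp_mask(const, blur_sigma = 3, amount = 2), const)
  se <- step_img(16, 0.3, 0.7)
  um <- unsharp_mask(se, blur_sigma = 2, amount = 1)
  expect_gt(max(um) - min(um), 0.4)  # overshoot beyond the 0.4 input swing
})

test_that("histogram modification recovers the inlier interval and clamps the lung minimum", {
  img <- outlier_img(seed = 1)
  out <- xm_histogram_modify(img, full_mask(100))
  # infer the effective linear map from interior pixels (oracle: the clip
  # rule's fixed point is the inlier interval [0.4, 0.6])
  interior <- img > 0.41 & img < 0.59
  fit <- stats::lm(as.vector(img[interior]) ~ as.vector(out[interior]))
  lo_hat <- unname(coef(fit)[1])
  hi_hat <- unname(coef(fit)[1] + coef(fit)[2])
  expect_lt(abs(lo_hat - 0.4), 0.005)
  expect_lt(abs(hi_hat - 0.6), 0.005)
  expect_equal(min(out), 0)
  expect_equal(max(out), 1)
})

test_that("histogram modification maps the lung minimum to zero and is monotone", {
  ph <- generate_phantom(phantom_spec(size = 128, abnormal = TRUE, seed = 9))
  out <- xm_histogram_modify(ph$image, ph$mask)
  expect_equal(min(out[ph$mask$mask]), 0)
  expect_equal(max(out), 1)
  inb <- out > 0 & out < 1   # strictly inside the final bounds
  ord <- order(ph$image[inb])
  expect_true(all(diff(out[inb][ord]) >= 0))
  const <- xm_histogram_modify(matrix(0.5, 64, 64), full_mask(64))
  expect_false(anyNA(const))
})

test_that("hist_mod_params validates its ranges", {
  expect_error(hist_mod_params(clip_frac = 0.2), "clip_frac")
  expect_error(hist_mod_params(max_iter = 0), "max_iter")
  expect_error(hist_mod_params(n_bins = 10), "n_bins")
})

test_that("resize to 512 preserves identity, constants, and means", {
  img512 <- rand_img(512, seed = 10)
  expect_lte(max(abs(resize_512(img512) - img512)), 1e-12)
  const <- resize_512(matrix(0.7, 100, 140))
  expect_equal(dim(const), c(512L, 512L))
  expect_lt(diff(range(const)), 1e-12)
  expect_equal(mean(const), 0.7)
  cb <- (matrix(seq_len(1024), 1024, 1024) +
           matrix(seq_len(1024), 1024, 1024, byrow = TRUE)) %% 2
  expect_lt(abs(mean(resize_512(cb)) - mean(cb)), 0.01)
})

test_that("dispatch applies crop/method/resize with shared contracts", {
  const <- preprocess_dispatch(matrix(0.4, 100, 100), method = "none")
  expect_equal(dim(const), c(512L, 512L))
  expect_lt(diff(range(const)), 1e-12)
  expect_equal(mean(const), 0.4)

  ph <- generate_phantom(phantom_spec(size = 96, seed = 12))
  for (m in c("none", "he", "clahe", "um", "xm")) {
    out <- preprocess_dispatch(ph$image, method = m, out_size = 64)
    expect_equal(dim(out), c(64L, 64L))
    expect_gte(min(out), 0)
    expect_lte(max(out), 1)
    expect_false(anyNA(out))
  }
  expect_error(preprocess_dispatch(ph$image, method = "sobel"), "unknown method")
})

test_that("repeated histogram modification is nearly idempotent", {
  ph <- generate_phantom(phantom_spec(size = 128, abnormal = TRUE, seed = 13))
  once <- preprocess_dispatch(ph$image, method = "xm", out_size = 128)
  twice <- preprocess_dispatch(once, method = "xm", out_size = 128)
  expect_lt(mean(abs(twice - once)), 0.05)
})
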