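test_that("phantom generation is deterministic per seed", {
  s <- phantom_spec(size = 96, abnormal = TRUE, seed = 17)
  a <- generate_phantom(s)
  b <- generate_phantom(s)
  expect_identical(a, b)
  c <- generate_phantom(phantom_spec(size = 96, abnormal = TRUE, seed = 18))
  expect_false(identical(a$image, c$image))
})

test_that("lesion sits inside the lung and carries its stated contrast", {
  for (kind in c("nodule", "consolidation")) {
    for (seed in c(4, 21)) {
      abn <- generate_phantom(phantom_spec(size = 128, abnormal = TRUE,
                                           lesion_kind = kind,
                                           lesion_contrast = 0.2, seed = seed))
      nrm <- generate_phantom(phantom_spec(size = 128, abnormal = FALSE,
                                           lesion_kind = kind,
                                           lesion_contrast = 0.2, seed = seed))
      expect_identical(abn$label, 1L)
      expect_identical(nrm$label, 0L)
      expect_true(all(abn$mask$mask[abn$lesion]))
      paired_diff <- mean(abn$image[abn$lesion]) - mean(nrm$image[abn$lesion])
      expect_gte(paired_diff, 0.5 * 0.2)
    }
  }
})

test_that("phantom images satisfy the normalized-image contract", {
  ph <- generate_phantom(phantom_spec(size = 64, seed = 1))
  expect_gte(min(ph$image), 0)
  expect_lte(max(ph$image), 1)
  expect_false(anyNA(ph$image))
  expect_error(phantom_spec(lesion_contrast = 0.8), "lesion_contrast")
  expect_error(phantom_spec(size = 16), "size")
})

test_that("machine profiles behave as stated", {
  img <- rand_img(64, seed = 2)
  profs <- machine_profiles()
  expect_identical(apply_machine_profile(img, profs$IDENTITY), img)

  gamma_only <- machine_profile("G", gamma = 1.3)
  expect_identical(apply_machine_profile(img, gamma_only),
                   gamma_contrast(img, 1.3))

  const <- matrix(0.5, 256, 256)
  noisy <- apply_machine_profile(const, machine_profile("N", noise_sigma = 0.05),
                                 seed = 5)
  expect_gte(sd(noisy - const), 0.045)
  expect_lte(sd(noisy - const), 0.055)
  expect_identical(noisy,
                   apply_machine_profile(const,
                                         machine_profile("N", noise_sigma = 0.05),
                                         seed = 5))
  expect_error(machine_profile("bad", gamma = -1), "gamma")
})

test_that("dataset generation honours counts, seeds, and contracts", {
  ds <- generate_dataset(100, abnormal_frac = 0.3, seed = 8, size = 64)
  expect_equal(sum(ds$labels), 30)
  ds2 <- generate_dataset(100, abnormal_frac = 0.3, seed = 8, size = 64)
  expect_identical(ds$manifest, ds2$manifest)
  expect_identical(ds$images, ds2$images)
  ok <- vapply(ds$images, function(im) {
    min(im) >= 0 && max(im) <= 1 && !anyNA(im)
  }, logical(1))
  expect_true(all(ok))
  expect_error(generate_dataset(10, abnormal_frac = 0.01), "rounds")
  expect_error(generate_dataset(1, abnormal_frac = 0.5), "n must be")
})

test_that("dataset export writes readable PNGs and a manifest", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(4, abnormal_frac = 0.5, seed = 3, size = 64, dir = dir)
  man <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 4)
  img <- to_normalized(read_image(file.path(dir, man$path[1])))
  expect_lte(max(abs(img - ds$images[[1]])), 1 / 65535 + 1e-12)
})

test_that("clean phantoms are separable by a simple lung-intensity statistic", {
  ds <- generate_dataset(100, abnormal_frac = 0.5, seed = 11, size = 128,
                         lesion_contrast = 0.2)
  stat <- vapply(seq_along(ds$images), function(i) {
    core <- xmpipe:::erode_disk(ds$masks[[i]]$mask, 6)
    if (!any(core)) core <- ds$masks[[i]]$mask
    v <- ds$images[[i]][core]
    quantile(v, 0.95, names = FALSE) - median(v)
  }, numeric(1))
  expect_gt(roc_auc(ds$labels, stat), 0.9)
})
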