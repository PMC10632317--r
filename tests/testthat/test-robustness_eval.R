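# brute-force pairwise AUC used as the independent oracle throughout
auc_brute <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  mean(outer(pos, neg, function(p, n) (p > n) + 0.5 * (p == n)))
}

test_that("roc_auc matches hand values and the pairwise oracle", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.1, 0.2)), 1.0)
  expect_equal(roc_auc(c(1, 1, 0, 0), rep(0.5, 4)), 0.5)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.8, 0.4, 0.6, 0.2)), 0.75)
  withr::with_seed(42, {
    for (i in 1:50) {
      n <- sample(4:50, 1)
      labels <- c(1, 0, rbinom(n - 2, 1, 0.5))
      scores <- round(runif(n), sample(1:3, 1))  # coarse rounding forces ties
      expect_equal(roc_auc(labels, scores), auc_brute(labels, scores),
                   tolerance = 1e-12)
    }
  })
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "degenerate")
})

test_that("complement symmetry: auc(scores) + auc(-scores) = 1", {
  withr::with_seed(7, {
    labels <- rbinom(40, 1, 0.5); labels[1:2] <- c(0, 1)
    scores <- runif(40)
    expect_equal(roc_auc(labels, scores) + roc_auc(labels, -scores), 1)
  })
})

test_that("delong_ci: degenerate separation, consistency, bootstrap oracle", {
  sep <- delong_ci(rep(c(1, 0), each = 5), c(6:10, 1:5) / 10)
  expect_equal(sep$auc, 1)
  expect_equal(sep$var, 0)
  expect_equal(sep$ci95, c(1, 1))

  withr::with_seed(3, {
    labels <- rep(c(1, 0), each = 100)
    scores <- c(rnorm(100, 1), rnorm(100, 0))
    res <- delong_ci(labels, scores)
    expect_identical(res$auc, roc_auc(labels, scores))
    boot <- replicate(2000, {
      i <- c(sample(1:100, replace = TRUE), sample(101:200, replace = TRUE))
      roc_auc(labels, scores[i])
    })
    expect_lt(abs(res$var / var(boot) - 1), 0.25)
    expect_true(res$ci95[1] <= res$auc && res$auc <= res$ci95[2])
  })
  expect_error(delong_ci(c(1, 0, 0), c(0.9, 0.1, 0.2)), "degenerate")
})

test_that("paired DeLong test: null identity, symmetry, degenerate flag", {
  labels <- rep(c(1, 0), each = 10)
  s <- withr::with_seed(1, runif(20))
  expect_equal(delong_paired_test(s, s, labels)$p_value, 1)

  s2 <- withr::with_seed(2, runif(20))
  ab <- delong_paired_test(s, s2, labels)
  ba <- delong_paired_test(s2, s, labels)
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(ab$statistic, -ba$statistic)

  # rank-preserving transform changes no placement: zero variance, zero diff
  expect_equal(delong_paired_test(s, s^3, labels)$p_value, 1)
})

test_that("Fisher combination matches the chi-square survival oracle", {
  r1 <- fisher_combine(rep(1, 3))
  expect_equal(r1$statistic, 0)
  expect_equal(r1$p_value, 1)

  r2 <- fisher_combine(c(0.5, 0.5))
  expect_equal(r2$statistic, 2.7726, tolerance = 1e-4)
  expect_equal(r2$p_value, 0.5966, tolerance = 1e-4)

  # independent oracle: survival of chi-square via the integrated density
  surv <- function(x, df) {
    stats::integrate(function(t) stats::dchisq(t, df), x, Inf)$value
  }
  for (p in list(0.2, c(0.1, 0.9), c(0.5, 0.2, 0.01, 0.7, 0.33))) {
    x <- -2 * sum(log(p))
    expect_equal(fisher_combine(p)$p_value, surv(x, 2 * length(p)),
                 tolerance = 1e-6)
  }

  expect_lt(fisher_combine(c(0.3, 0.5))$p_value,
            fisher_combine(c(0.5, 0.5))$p_value)
  expect_error(fisher_combine(c(0.5, 1.2)), "p-values")
  expect_warning(r0 <- fisher_combine(c(0, 0.5)), "clamped")
  expect_lt(r0$p_value, 1e-10)
})

test_that("under-sampling balances classes reproducibly", {
  labels <- c(rep(0, 70), rep(1, 30))
  idx <- undersample_majority(labels, seed = 4)
  expect_equal(sum(labels[idx] == 0), 30)
  expect_equal(sum(labels[idx] == 1), 30)
  expect_true(all(which(labels == 1) %in% idx))
  expect_identical(idx, undersample_majority(labels, seed = 4))
  balanced <- rep(c(0, 1), 10)
  expect_identical(undersample_majority(balanced, 1), seq_along(balanced))
  expect_error(undersample_majority(rep(1, 10)), "both classes")
})

test_that("repeated splits partition the pool at the stated sizes", {
  sp <- repeated_splits(7202, k = 3, train_frac = 0.8, seed = 5)
  for (s in sp) {
    expect_equal(length(s$train), 5762)
    expect_equal(length(s$val), 1440)
    expect_equal(sort(c(s$train, s$val)), 1:7202)
    expect_length(intersect(s$train, s$val), 0)
  }
  expect_false(identical(sp[[1]]$train, sp[[2]]$train))
  expect_identical(sp, repeated_splits(7202, k = 3, train_frac = 0.8, seed = 5))
})

test_that("reference classifier learns separable phantoms deterministically", {
  ds <- generate_dataset(60, abnormal_frac = 0.5, seed = 21, size = 96,
                         lesion_contrast = 0.25)
  clf <- train_reference_classifier(ds$images, ds$labels, preprocess = "none",
                                    augment = NULL, seed = 1)
  expect_gt(roc_auc(ds$labels, score_images(clf, ds$images)), 0.9)
  clf2 <- train_reference_classifier(ds$images, ds$labels, preprocess = "none",
                                     augment = NULL, seed = 1)
  expect_identical(clf$weights, clf2$weights)
  expect_error(train_reference_classifier(ds$images, rep(1, 60),
                                          preprocess = "none"),
               "degenerate")
  expect_error(train_reference_classifier(ds$images[1:10], ds$labels[1:10],
                                          preprocess = "none"),
               "at least 20")
})

test_that("classifier JSON round-trip preserves scores", {
  ds <- generate_dataset(24, abnormal_frac = 0.5, seed = 2, size = 64)
  clf <- train_reference_classifier(ds$images, ds$labels, preprocess = "he",
                                    augment = NULL, seed = 3)
  f <- withr::local_tempfile(fileext = ".json")
  save_classifier(clf, f)
  back <- load_classifier(f)
  expect_equal(score_images(back, ds$images[1:3]),
               score_images(clf, ds$images[1:3]))
})

test_that("perturbation sweep: identity point, shapes, noise degradation", {
  ds <- generate_dataset(60, abnormal_frac = 0.5, seed = 5, size = 96,
                         lesion_contrast = 0.2)
  model <- function(img) {
    m <- segment_lungs(img)
    core <- xmpipe:::erode_disk(m$mask, 5)
    if (!any(core)) core <- m$mask
    v <- img[core]
    quantile(v, 0.95, names = FALSE) - median(v)
  }
  base_auc <- roc_auc(ds$labels, vapply(ds$images, model, numeric(1)))

  sg <- perturbation_sweep(model, ds$images, ds$labels, axis = "gamma",
                           grid = c(0.5, 1, 2), n_repeats = 3, seed = 6)
  expect_length(sg$auc_mean, 3)
  expect_equal(nrow(sg$auc_ci), 3)
  expect_equal(sg$auc_mean[2], base_auc)  # identity grid point, noiseless axis

  sn <- perturbation_sweep(model, ds$images, ds$labels, axis = "noise",
                           grid = c(0, 0.05, 0.1), n_repeats = 5, seed = 6)
  ci_w <- sn$auc_ci[, 2] - sn$auc_ci[, 1]
  expect_lte(sn$auc_mean[3], sn$auc_mean[1] + ci_w[3] + 0.02)

  expect_error(perturbation_sweep(model, ds$images, ds$labels, axis = "gamma",
                                  grid = c(2, 3), n_repeats = 2, seed = 1),
               "identity")
  f <- withr::local_tempfile(fileext = ".csv")
  write_sweep_csv(sn, f)
  back <- read.csv(f, comment.char = "#")
  expect_equal(back$auc_mean, sn$auc_mean)
})
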