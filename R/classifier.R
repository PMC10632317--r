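# Desk-scale reference classifier.
#
# Stands in for the GPU-trained deep network, which is out of scope here:
# each image runs through the chosen pre-processing pipeline, is
# downsampled to a small feature grid, and a ridge-penalized logistic
# regression (glmnet, fixed lambda, no CV for determinism) maps the grid to
# an abnormality score in [0,1]. The point is not absolute performance but
# that the classifier inherits the robustness (or fragility) of the
# pipeline in front of it.

#' Train the reference classifier
#'
#' For every training image: segment the lungs, apply the pre-processing
#' pipeline at `work_size`, then add `n_aug` augmented copies. The
#' gamma/sharpness/noise draw of each copy is applied to the *raw* image
#' before pre-processing — these augmentations mimic acquisition-hardware
#' variation, which physically precedes any pre-processing — while the
#' geometric rotation/flip draw is applied to the pre-processed result.
#' Features are the `feat_size^2` bilinear downsample; the model is a ridge
#' logistic regression. Scoring a new image repeats segmentation +
#' pre-processing, so test-time images are normalized exactly as in
#' training.
#'
#' @param images list of numeric matrices on `[0,1]`.
#' @param labels 0/1 vector, both classes present; at least 20 images.
#' @param preprocess one of `"none"`, `"he"`, `"clahe"`, `"um"`, `"xm"`.
#' @param augment an [augment_params()] object, or `NULL` for none.
#' @param seed integer seed (augmentation draws and noise).
#' @param n_aug augmented copies per image (default 2; ignored without
#'   `augment`).
#' @param feat_size feature grid side (default 16).
#' @param work_size pre-processing output side (default 64; the full-scale
#'   contract value 512 is supported but slower).
#' @param lambda ridge penalty (default 0.01).
#' @return object of class `xm_classifier`.
#' @export
train_reference_classifier <- function(images, labels, preprocess = "xm",
                                       augment = NULL, seed = 1L, n_aug = 2L,
                                       feat_size = 16L, work_size = 64L,
                                       lambda = 0.01) {
  check_that(is.list(images) && length(images) == length(labels),
             "images and labels differ in length")
  check_that(length(images) >= 20L, "need at least 20 images")
  check_that(all(labels %in% c(0, 1)), "labels must be 0/1")
  check_that(length(unique(labels)) == 2L,
             "degenerate input: both classes must be present")
  n <- length(images)
  aug_seeds <- with_seed(seed, matrix(sample.int(2^30, n * max(n_aug, 1L)),
                                      nrow = n))
  rows <- list(); y <- integer(0)
  for (i in seq_len(n)) {
    base <- preprocess_dispatch(images[[i]], method = preprocess,
                                out_size = work_size)
    feats <- list(as.vector(resize_image(base, feat_size, feat_size)))
    if (!is.null(augment)) {
      for (j in seq_len(n_aug)) {
        sd_ij <- aug_seeds[i, j]
        draw <- sample_augmentation(augment, rng_seed = sd_ij)
        pert <- apply_perturbation(images[[i]], draw$spec, seed = sd_ij)
        aug <- preprocess_dispatch(pert, method = preprocess,
                                   out_size = work_size)
        aug <- rotate_flip(aug, draw$degrees, draw$flip)
        feats <- c(feats, list(as.vector(resize_image(aug, feat_size, feat_size))))
      }
    }
    rows <- c(rows, feats)
    y <- c(y, rep.int(labels[i], length(feats)))
  }
  X <- do.call(rbind, rows)
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0, lambda = lambda,
                        standardize = TRUE)
  beta <- as.numeric(fit$beta)
  structure(list(weights = beta, intercept = as.numeric(fit$a0),
                 preprocess = preprocess, feat_size = as.integer(feat_size),
                 work_size = as.integer(work_size), lambda = lambda,
                 seed = as.integer(seed)),
            class = "xm_classifier")
}

#' @export
print.xm_classifier <- function(x, ...) {
  cat(sprintf("<xm_classifier> preprocess='%s', %dx%d features, work size %d\n",
              x$preprocess, x$feat_size, x$feat_size, x$work_size))
  invisible(x)
}

#' Score images with a reference classifier
#'
#' @param clf an `xm_classifier`.
#' @param images a single matrix or a list of matrices on `[0,1]`.
#' @return numeric vector of abnormality scores in `[0,1]`.
#' @export
score_images <- function(clf, images) {
  check_that(inherits(clf, "xm_classifier"), "clf must be an xm_classifier")
  if (is.matrix(images)) images <- list(images)
  vapply(images, function(img) {
    base <- preprocess_dispatch(img, method = clf$preprocess,
                                out_size = clf$work_size)
    f <- as.vector(resize_image(base, clf$feat_size, clf$feat_size))
    1 / (1 + exp(-(clf$intercept + sum(clf$weights * f))))
  }, numeric(1))
}

#' Save / load a reference classifier as plain JSON
#'
#' @param clf an `xm_classifier`.
#' @param path JSON file path.
#' @export
save_classifier <- function(clf, path) {
  check_that(inherits(clf, "xm_classifier"), "clf must be an xm_classifier")
  jsonlite::write_json(unclass(clf), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(obj[c("weights", "intercept", "preprocess", "feat_size",
                  "work_size", "lambda", "seed")],
            class = "xm_classifier")
}

as_scorer <- function(model) {
  if (inherits(model, "xm_classifier")) {
    function(imgs) score_images(model, imgs)
  } else if (is.function(model)) {
    function(imgs) {
      if (is.matrix(imgs)) imgs <- list(imgs)
      vapply(imgs, model, numeric(1))
    }
  } else {
    stopf("model must be an xm_classifier or a function(image) -> score")
  }
}

SWEEP_IDENTITY <- c(gamma = 1, sharp = 0, noise = 0)

#' Single-axis perturbation sweep
#'
#' For every grid value, every evaluation image is perturbed along one axis
#' (the other two held at identity) *before* entering the model's own
#' pre-processing, mimicking an acquisition-side change; AUC is computed at
#' each point. The noise axis is repeated `n_repeats` times with fresh
#' noise seeds and summarized by a normal-approximation CI across repeats;
#' the deterministic axes produce identical repeats (zero-width CI).
#'
#' @param model an `xm_classifier` or a `function(image) -> score`.
#' @param images list of evaluation images.
#' @param labels 0/1 vector, both classes present.
#' @param axis `"gamma"`, `"sharp"` or `"noise"`.
#' @param grid strictly increasing parameter values containing the axis
#'   identity (1 for gamma, 0 for sharp/noise).
#' @param n_repeats repeats for the CI (default 10).
#' @param seed integer seed.
#' @return list of class `sweep_result`: `axis`, `grid`, `auc_mean`,
#'   `auc_ci` (matrix `length(grid) x 2`), `n_repeats`.
#' @export
perturbation_sweep <- function(model, images, labels,
                               axis = c("gamma", "sharp", "noise"), grid,
                               n_repeats = 10L, seed = 1L) {
  axis <- match.arg(axis)
  check_that(all(labels %in% c(0, 1)) && length(unique(labels)) == 2L,
             "degenerate input: both classes must be present")
  check_that(length(grid) >= 1L && !is.unsorted(grid, strictly = TRUE),
             "grid must be strictly increasing")
  check_that(any(abs(grid - SWEEP_IDENTITY[[axis]]) < 1e-12),
             "grid must contain the identity value of its axis")
  scorer <- as_scorer(model)
  n <- length(images)
  stochastic <- axis == "noise"
  rep_seeds <- with_seed(seed, matrix(sample.int(2^30, n_repeats * n),
                                      nrow = n_repeats))
  auc_mean <- numeric(length(grid))
  auc_ci <- matrix(NA_real_, length(grid), 2,
                   dimnames = list(NULL, c("lo", "hi")))
  for (g in seq_along(grid)) {
    spec <- switch(axis,
                   gamma = perturb_spec(gamma = grid[g]),
                   sharp = perturb_spec(sharp = grid[g]),
                   noise = perturb_spec(noise_sigma = grid[g]))
    reps <- if (stochastic && grid[g] > 0) n_repeats else 1L
    aucs <- vapply(seq_len(reps), function(r) {
      pert <- lapply(seq_len(n), function(i) {
        apply_perturbation(images[[i]], spec, seed = rep_seeds[r, i])
      })
      roc_auc(labels, scorer(pert))
    }, numeric(1))
    aucs <- rep_len(aucs, n_repeats)
    m <- mean(aucs)
    se <- sd(aucs) / sqrt(n_repeats)
    if (!is.finite(se)) se <- 0
    auc_mean[g] <- m
    auc_ci[g, ] <- pmin(pmax(m + c(-1, 1) * qnorm(0.975) * se, 0), 1)
  }
  structure(list(axis = axis, grid = grid, auc_mean = auc_mean,
                 auc_ci = auc_ci, n_repeats = as.integer(n_repeats)),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> axis %s, %d grid points, %d repeats\n",
              x$axis, length(x$grid), x$n_repeats))
  print(data.frame(grid = x$grid, auc_mean = round(x$auc_mean, 4),
                   ci_lo = round(x$auc_ci[, 1], 4),
                   ci_hi = round(x$auc_ci[, 2], 4)))
  invisible(x)
}

#' Write a sweep result as CSV
#'
#' Columns: `grid_value, auc_mean, ci_lo, ci_hi`, preceded by a versioned
#' comment header.
#'
#' @param sweep a `sweep_result`.
#' @param path output CSV path.
#' @export
write_sweep_csv <- function(sweep, path) {
  check_that(inherits(sweep, "sweep_result"), "sweep must be a sweep_result")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# xmpipe sweep v%s axis=%s repeats=%d",
                     as.character(utils::packageVersion("xmpipe")),
                     sweep$axis, sweep$n_repeats), con)
  write.csv(data.frame(grid_value = sweep$grid, auc_mean = sweep$auc_mean,
                       ci_lo = sweep$auc_ci[, 1], ci_hi = sweep$auc_ci[, 2]),
            con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Hardware-robustness benchmark on phantoms
#'
#' The scaled-down analogue of the stability comparison: for each of
#' `n_seeds` seeds, generate `n` phantoms, split 80/20, train two reference
#' classifiers on the training part — the robust arm (XM histogram
#' modification + rotation/flip + gamma/sharpness/noise augmentation) and a
#' conventional arm (HE + rotation/flip only) — and measure the validation
#' AUC of both arms on clean images and under the two stress points gamma =
#' 5 and sigma = 0.1 applied before each arm's own pre-processing.
#'
#' @param n phantoms per seed (default 200).
#' @param size phantom side (default 128).
#' @param lesion_contrast lesion contrast (default 0.2).
#' @param n_seeds number of independent repetitions (default 10).
#' @param seed master seed.
#' @return data.frame with one row per repetition: clean, gamma5 and
#'   sigma01 AUC for both arms.
#' @export
robustness_benchmark <- function(n = 200L, size = 128L, lesion_contrast = 0.2,
                                 n_seeds = 10L, seed = 1L) {
  seeds <- with_seed(seed, sample.int(2^30, n_seeds))
  res <- lapply(seq_len(n_seeds), function(k) {
    sk <- seeds[k]
    ds <- generate_dataset(n, abnormal_frac = 0.5, seed = sk, size = size,
                           lesion_contrast = lesion_contrast)
    # distinct sub-seed: the same seed would make the split permutation
    # collide with the dataset's abnormal-index draw
    sp <- stratified_ok_split(ds$labels, train_frac = 0.8, seed = sk + 1L)
    tr_img <- ds$images[sp$train]; tr_lab <- ds$labels[sp$train]
    va_img <- ds$images[sp$val]; va_lab <- ds$labels[sp$val]
    xm <- train_reference_classifier(tr_img, tr_lab, preprocess = "xm",
                                     augment = augment_params(), seed = sk)
    conv <- train_reference_classifier(tr_img, tr_lab, preprocess = "he",
                                       augment = augment_params(
                                         enabled = c("rotate", "flip")),
                                       seed = sk)
    eval_at <- function(clf, spec) {
      pert <- lapply(seq_along(va_img), function(i) {
        if (is.null(spec)) va_img[[i]] else
          apply_perturbation(va_img[[i]], spec, seed = sk + i)
      })
      roc_auc(va_lab, score_images(clf, pert))
    }
    data.frame(seed = sk,
               xm_clean = eval_at(xm, NULL),
               conv_clean = eval_at(conv, NULL),
               xm_gamma5 = eval_at(xm, perturb_spec(gamma = 5)),
               conv_gamma5 = eval_at(conv, perturb_spec(gamma = 5)),
               xm_sigma01 = eval_at(xm, perturb_spec(noise_sigma = 0.1)),
               conv_sigma01 = eval_at(conv, perturb_spec(noise_sigma = 0.1)))
  })
  do.call(rbind, res)
}
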