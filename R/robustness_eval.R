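# Evaluation protocol: ROC AUC via the Mann-Whitney statistic, DeLong
# variance and paired test, Fisher p-value combination across repeated
# splits, majority-class under-sampling, and shared 80/20 split generation.

check_labeled_scores <- function(labels, scores, min_per_class = 1L) {
  check_that(length(labels) == length(scores), "labels and scores differ in length")
  check_that(all(labels %in% c(0, 1)), "labels must be 0/1")
  check_that(all(is.finite(scores)), "scores must be finite")
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  check_that(n_pos >= min_per_class && n_neg >= min_per_class,
             "degenerate input: need at least %d observation(s) per class",
             min_per_class)
  invisible(c(n_pos, n_neg))
}

#' ROC AUC (Mann-Whitney statistic)
#'
#' Mean over all (positive, negative) pairs of `[s_p > s_n] + 0.5*[s_p ==
#' s_n]`, computed from midranks.
#'
#' @param labels 0/1 vector.
#' @param scores numeric vector, same length.
#' @return AUC in `[0,1]`.
#' @export
roc_auc <- function(labels, scores) {
  n <- check_labeled_scores(labels, scores)
  r <- rank(scores)
  (sum(r[labels == 1]) - n[1] * (n[1] + 1) / 2) / (n[1] * n[2])
}

# DeLong placement values: V10 (per positive) and V01 (per negative)
delong_placements <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  m <- length(pos); n <- length(neg)
  r_all <- rank(c(pos, neg))
  v10 <- (r_all[seq_len(m)] - rank(pos)) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(neg)) / m
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' AUC with DeLong variance and confidence interval
#'
#' Nonparametric variance from the DeLong structural components (empirical
#' variances of the per-positive and per-negative placement values), with a
#' normal-approximation CI clipped to `[0,1]`.
#'
#' @param labels 0/1 vector with at least two observations per class.
#' @param scores numeric vector.
#' @param level confidence level (default 0.95).
#' @return list of class `eval_result`: `auc`, `var`, `ci95`, `n_pos`,
#'   `n_neg`.
#' @export
delong_ci <- function(labels, scores, level = 0.95) {
  n <- check_labeled_scores(labels, scores, min_per_class = 2L)
  pl <- delong_placements(labels, scores)
  v <- var(pl$v10) / n[1] + var(pl$v01) / n[2]
  z <- qnorm(1 - (1 - level) / 2)
  ci <- pmin(pmax(pl$auc + c(-1, 1) * z * sqrt(v), 0), 1)
  structure(list(auc = pl$auc, var = v, ci95 = ci,
                 n_pos = n[1], n_neg = n[2]),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("AUC %.4f (%.0f%% CI %.4f-%.4f), n_pos=%d, n_neg=%d\n",
              x$auc, 95, x$ci95[1], x$ci95[2], x$n_pos, x$n_neg))
  invisible(x)
}

#' Paired DeLong test for two correlated AUCs
#'
#' Two-sided normal-approximation test of the AUC difference of two models
#' scoring the same cases; the covariance between the two AUCs comes from
#' the paired placement values. Identical score vectors give p = 1; a zero
#' variance with a nonzero difference is reported as p = 0 with
#' `degenerate = TRUE`.
#'
#' @param scores_a,scores_b scores of the two models on the same cases.
#' @param labels shared 0/1 labels.
#' @return list of class `delong_test`: `p_value`, `statistic` (z),
#'   `auc_a`, `auc_b`, `degenerate`.
#' @export
delong_paired_test <- function(scores_a, scores_b, labels) {
  check_labeled_scores(labels, scores_a, min_per_class = 2L)
  check_labeled_scores(labels, scores_b, min_per_class = 2L)
  pa <- delong_placements(labels, scores_a)
  pb <- delong_placements(labels, scores_b)
  m <- length(pa$v10); n <- length(pa$v01)
  v_diff <- var(pa$v10 - pb$v10) / m + var(pa$v01 - pb$v01) / n
  d <- pa$auc - pb$auc
  degenerate <- FALSE
  if (v_diff <= 0) {
    if (abs(d) < .Machine$double.eps^0.5) {
      p <- 1; z <- 0
    } else {
      p <- 0; z <- Inf * sign(d); degenerate <- TRUE
    }
  } else {
    z <- d / sqrt(v_diff)
    p <- 2 * pnorm(-abs(z))
  }
  structure(list(p_value = p, statistic = z, auc_a = pa$auc, auc_b = pb$auc,
                 degenerate = degenerate),
            class = "delong_test")
}

#' @export
print.delong_test <- function(x, ...) {
  cat(sprintf("paired DeLong: AUC %.4f vs %.4f, z = %.3f, p = %.4g%s\n",
              x$auc_a, x$auc_b, x$statistic, x$p_value,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Fisher's method for combining p-values
#'
#' `X = -2 * sum(log(p_i))` referred to a chi-square distribution with `2k`
#' degrees of freedom (survival function). Independence across the combined
#' tests is assumed; with overlapping data splits this is an approximation.
#' Exact zeros are clamped to machine epsilon with a warning.
#'
#' @param pvalues vector of p-values in `(0, 1]`.
#' @return list: `statistic`, `df`, `p_value`.
#' @export
fisher_combine <- function(pvalues) {
  check_that(length(pvalues) >= 1L, "need at least one p-value")
  check_that(all(is.finite(pvalues)) && all(pvalues >= 0) && all(pvalues <= 1),
             "p-values must lie in (0, 1]")
  if (any(pvalues == 0)) {
    warning("p-value of exactly 0 clamped to machine epsilon before log")
    pvalues[pvalues == 0] <- .Machine$double.eps
  }
  x <- -2 * sum(log(pvalues))
  df <- 2L * length(pvalues)
  list(statistic = x, df = df, p_value = pchisq(x, df, lower.tail = FALSE))
}

#' Under-sample the majority class
#'
#' Keeps every minority-class index plus a uniform random subset of the
#' majority class of equal size; already balanced data is returned intact.
#'
#' @param labels 0/1 vector.
#' @param seed integer seed.
#' @return sorted integer index vector into `labels`.
#' @export
undersample_majority <- function(labels, seed = 1L) {
  check_that(all(labels %in% c(0, 1)), "labels must be 0/1")
  check_that(length(unique(labels)) == 2L, "both classes must be present")
  idx1 <- which(labels == 1); idx0 <- which(labels == 0)
  if (length(idx1) == length(idx0)) return(seq_along(labels))
  minority <- if (length(idx1) < length(idx0)) idx1 else idx0
  majority <- if (length(idx1) < length(idx0)) idx0 else idx1
  kept <- with_seed(seed, sample(majority, length(minority)))
  sort(c(minority, kept))
}

#' Repeated random train/validation splits
#'
#' `k` independent shuffles of the pool, each partitioned into a training
#' set of `round(train_frac * n_pool)` and the complement. One seed fully
#' determines all `k` splits, so different model settings can share the
#' identical division of the data.
#'
#' @param n_pool pool size.
#' @param k number of repeats (default 10).
#' @param train_frac training fraction in `(0,1)` (default 0.8).
#' @param seed integer seed.
#' @return list of `k` lists with sorted integer `train` and `val`.
#' @export
repeated_splits <- function(n_pool, k = 10L, train_frac = 0.8, seed = 1L) {
  check_that(is_count(n_pool, 2L), "n_pool must be >= 2")
  check_that(is_count(k), "k must be >= 1")
  check_that(train_frac > 0 && train_frac < 1, "train_frac must be in (0,1)")
  n_train <- round(train_frac * n_pool)
  check_that(n_train >= 1 && n_train < n_pool, "split leaves an empty part")
  with_seed(seed, lapply(seq_len(k), function(i) {
    perm <- sample.int(n_pool)
    list(train = sort(perm[seq_len(n_train)]),
         val = sort(perm[(n_train + 1):n_pool]))
  }))
}

# one split whose parts both contain both classes; deterministically retries
# with derived seeds (relevant only for small pools)
stratified_ok_split <- function(labels, train_frac, seed) {
  for (try in 0:50) {
    sp <- repeated_splits(length(labels), k = 1L, train_frac = train_frac,
                          seed = seed + try * 1000003L)[[1]]
    if (length(unique(labels[sp$train])) == 2L &&
        length(unique(labels[sp$val])) == 2L) {
      return(sp)
    }
  }
  stopf("could not find a split with both classes in both parts")
}
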