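# Lung-field localization.
#
# A deterministic classical stand-in for a learned lung segmenter: Otsu
# threshold on the intensity histogram, binary opening/closing with a disk
# (radius 1% of the short image side), then the largest one or two dark
# components whose centroids sit in the central 80% of columns. Lungs are
# the dark (aerated) regions under the display-orientation convention; a
# polarity flag allows override. A centered-rectangle fallback makes the
# operation total, which the histogram-modification clamp relies on.

#' Otsu threshold of a [0,1] image
#'
#' Maximizes between-class variance on a 256-bin histogram.
#'
#' @param img numeric matrix on `[0,1]`.
#' @return threshold in `[0,1]`.
#' @export
otsu_threshold <- function(img) {
  check_norm_image(img)
  counts <- tabulate(pmin(floor(as.vector(img) * 256) + 1L, 256L), 256L)
  p <- counts / sum(counts)
  mids <- (seq_len(256) - 0.5) / 256
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[256]
  between <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

disk_offsets <- function(r) {
  d <- expand.grid(dr = -r:r, dc = -r:r)
  d[d$dr^2 + d$dc^2 <= r^2 + 1e-9, , drop = FALSE]
}

shift_mask <- function(m, dr, dc, fill) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

dilate_disk <- function(mask, r) {
  off <- disk_offsets(r)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(off))) {
    out <- out | shift_mask(mask, off$dr[i], off$dc[i], FALSE)
  }
  out
}

erode_disk <- function(mask, r) {
  off <- disk_offsets(r)
  out <- matrix(TRUE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(off))) {
    out <- out & shift_mask(mask, off$dr[i], off$dc[i], FALSE)
  }
  out
}

binary_open <- function(mask, r) dilate_disk(erode_disk(mask, r), r)
binary_close <- function(mask, r) erode_disk(dilate_disk(mask, r), r)

# 4-connected component labelling via row runs + union-find.
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  runs_row <- integer(0); runs_c0 <- integer(0); runs_c1 <- integer(0)
  for (i in seq_len(h)) {
    rl <- rle(mask[i, ])
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    keep <- rl$values
    if (any(keep)) {
      runs_row <- c(runs_row, rep.int(i, sum(keep)))
      runs_c0 <- c(runs_c0, starts[keep])
      runs_c1 <- c(runs_c1, ends[keep])
    }
  }
  nr <- length(runs_row)
  labels <- matrix(0L, h, w)
  if (nr == 0L) return(list(labels = labels, sizes = integer(0)))
  parent <- seq_len(nr)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  prev <- integer(0)
  row_of_prev <- -1L
  for (i in seq_len(nr)) {
    if (runs_row[i] != row_of_prev) {
      prev <- which(runs_row == runs_row[i] - 1L)
      row_of_prev <- runs_row[i]
    }
    for (j in prev) {
      if (runs_c0[i] <= runs_c1[j] && runs_c1[i] >= runs_c0[j]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(nr), find, integer(1))
  ids <- match(roots, unique(roots))
  for (i in seq_len(nr)) {
    labels[runs_row[i], runs_c0[i]:runs_c1[i]] <- ids[i]
  }
  sizes <- tabulate(labels[labels > 0L])
  list(labels = labels, sizes = sizes)
}

new_lung_mask <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  stopifnot(nrow(idx) > 0L)
  # 0-based half-open bounding box: rows [r0, r1), cols [c0, c1)
  bbox <- c(min(idx[, 1]) - 1L, min(idx[, 2]) - 1L, max(idx[, 1]), max(idx[, 2]))
  structure(list(mask = mask, bbox = as.integer(bbox),
                 area_fraction = mean(mask)),
            class = "lung_mask")
}

#' @export
print.lung_mask <- function(x, ...) {
  cat(sprintf("<lung_mask> %dx%d, bbox [%d,%d)x[%d,%d), area %.3f\n",
              nrow(x$mask), ncol(x$mask), x$bbox[1], x$bbox[3], x$bbox[2],
              x$bbox[4], x$area_fraction))
  invisible(x)
}

#' Segment the lung fields
#'
#' Deterministic classical segmentation standing in for a learned lung
#' cropper, which must stay reliable across machines with very different
#' contrast. The image is therefore contrast-normalized first — a 1%
#' percentile re-stretch followed by a power transform anchoring the
#' median at 0.5, which approximately inverts monotone gamma distortions —
#' then Otsu-thresholded, cleaned by opening + closing with a disk of
#' radius 1% of the short side, and reduced to the largest one or two
#' components (each at least 5% of image area) whose centroid columns lie
#' in the central 80% of the image. If nothing qualifies, a centered
#' rectangle covering 60% of each dimension is returned, so the result is
#' never empty.
#'
#' @param img numeric matrix on `[0,1]`.
#' @param polarity `"dark"` (default): lungs are below the threshold, the
#'   display-orientation convention. `"bright"` flips the candidate set.
#' @return a `lung_mask`: logical `mask`, 0-based half-open `bbox`
#'   `(row0, col0, row1, col1)`, and `area_fraction`.
#' @export
segment_lungs <- function(img, polarity = c("dark", "bright")) {
  polarity <- match.arg(polarity)
  check_norm_image(img)
  h <- nrow(img); w <- ncol(img)
  fallback <- function() {
    m <- matrix(FALSE, h, w)
    r0 <- floor(h * 0.2); c0 <- floor(w * 0.2)
    m[(r0 + 1):(r0 + round(0.6 * h)), (c0 + 1):(c0 + round(0.6 * w))] <- TRUE
    new_lung_mask(m)
  }
  # contrast-normalize before thresholding: percentile stretch, then anchor
  # the median at 0.5 so monotone gamma changes barely move the threshold
  b <- tail_bounds(img, 0.01, 1024L)
  norm <- clamp01((img - b[1]) / max(b[2] - b[1], 1e-6))
  med <- min(max(median(norm), 0.01), 0.99)
  norm <- norm^(log(0.5) / log(med))
  thr <- otsu_threshold(norm)
  cand <- if (polarity == "dark") norm < thr else norm > thr
  if (!any(cand) || all(cand)) return(fallback())
  r <- max(1L, round(0.01 * min(h, w)))
  cand <- binary_close(binary_open(cand, r), r)
  if (!any(cand)) return(fallback())
  lab <- label_components(cand)
  if (length(lab$sizes) == 0L) return(fallback())
  # centroid-column filter: keep components centred in the middle 80%
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  cen <- vapply(seq_along(lab$sizes), function(k) {
    mean(cols[lab$labels == k])
  }, numeric(1))
  central <- which(cen >= 0.1 * w & cen <= 0.9 * w)
  big <- central[lab$sizes[central] >= 0.05 * h * w]
  if (length(big) == 0L) return(fallback())
  keep <- big[order(lab$sizes[big], decreasing = TRUE)][seq_len(min(2L, length(big)))]
  new_lung_mask(matrix(lab$labels %in% keep, h, w))
}

#' Crop an image to the lung bounding box
#'
#' Expands the mask's bounding box by `margin_frac` of its own height and
#' width, clips to the image, and crops image and mask consistently.
#'
#' @param img numeric matrix on `[0,1]`.
#' @param mask a `lung_mask` for `img`.
#' @param margin_frac margin as a fraction of bbox size, in `[0, 0.5]`.
#' @return list with `image` and `mask` (a re-derived `lung_mask`).
#' @export
crop_to_lungs <- function(img, mask, margin_frac = 0.05) {
  check_norm_image(img)
  check_that(inherits(mask, "lung_mask"), "mask must be a lung_mask")
  check_that(all(dim(mask$mask) == dim(img)), "mask shape must match image")
  check_that(margin_frac >= 0 && margin_frac <= 0.5,
             "margin_frac must be in [0, 0.5]")
  b <- mask$bbox
  bh <- b[3] - b[1]; bw <- b[4] - b[2]
  r0 <- max(0L, b[1] - round(margin_frac * bh))
  c0 <- max(0L, b[2] - round(margin_frac * bw))
  r1 <- min(nrow(img), b[3] + round(margin_frac * bh))
  c1 <- min(ncol(img), b[4] + round(margin_frac * bw))
  rows <- (r0 + 1):r1; cols <- (c0 + 1):c1
  list(image = img[rows, cols, drop = FALSE],
       mask = new_lung_mask(mask$mask[rows, cols, drop = FALSE]))
}

#' Write a binary mask as an 8-bit PNG (0/255)
#'
#' @param mask a `lung_mask` or logical matrix.
#' @param path output PNG path.
#' @export
write_mask_png <- function(mask, path) {
  m <- if (inherits(mask, "lung_mask")) mask$mask else mask
  png::writePNG(m * 1, path)
  invisible(path)
}
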