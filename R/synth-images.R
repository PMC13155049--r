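#' Generator settings for synthetic histology-like patches
#'
#' Defines the morphology of the two classes. Benign patches contain a handful
#' of sparse, round, low-contrast blobs on a pale eosin-pink background.
#' Malignant patches additionally contain 1-3 clusters of 20-60 overlapping,
#' irregular, strongly hematoxylin-dark blobs -- emulating the densely packed
#' nuclei that drive malignancy calls in real H&E patches -- and the closed
#' footprint of those clusters is recorded as the ground-truth tumor mask.
#'
#' @param height,width patch size in pixels (>= 32).
#' @param contrast minimum guaranteed difference in mean grey intensity between
#'   pixels inside and outside the planted tumor mask (on the \[0,1\] scale).
#' @param background base RGB color of the tissue background.
#' @param noise_sd standard deviation of per-pixel Gaussian texture noise.
#' @param benign,malignant per-class morphology settings; ranges are
#'   `c(lo, hi)` pairs sampled uniformly per image.
#' @return a `generator_params` list.
#' @export
generator_params <- function(height = 64L, width = 64L,
                             contrast = 0.2,
                             background = c(0.92, 0.80, 0.86),
                             noise_sd = 0.015,
                             benign = list(n_blobs = c(5L, 15L),
                                           radius = c(0.030, 0.060),
                                           irregularity = 0.05,
                                           color = c(0.72, 0.55, 0.74),
                                           alpha = 0.5),
                             malignant = list(n_clusters = c(1L, 3L),
                                              blobs_per_cluster = c(20L, 60L),
                                              cluster_radius = c(0.12, 0.20),
                                              blob_radius = c(0.020, 0.045),
                                              irregularity = 0.4,
                                              color = c(0.32, 0.12, 0.42),
                                              alpha = 0.9)) {
  if (height < 32 || width < 32) {
    stop_config("patch size must be at least 32x32, got ", height, "x", width)
  }
  for (rg in list(benign$n_blobs, benign$radius, malignant$n_clusters,
                  malignant$blobs_per_cluster, malignant$cluster_radius,
                  malignant$blob_radius)) {
    if (length(rg) != 2 || any(!is.finite(rg)) || rg[1] > rg[2]) {
      stop_config("generator ranges must be finite c(lo, hi) pairs with lo <= hi")
    }
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 contrast = contrast, background = background,
                 noise_sd = noise_sd, benign = benign, malignant = malignant),
            class = "generator_params")
}

new_labeled_image <- function(pixels, label, gt_mask, patient_id = NA_character_) {
  structure(list(pixels = pixels, label = as.integer(label),
                 gt_mask = gt_mask, patient_id = patient_id),
            class = "labeled_image")
}

# raster a single irregular blob into logical mask `acc`, restricted to its
# bounding box; radius is modulated sinusoidally with angle for irregularity
blob_mask <- function(h, w, cy, cx, r0, irregularity, lobes, phase) {
  rmax <- r0 * (1 + abs(irregularity))
  ys <- max(1L, floor(cy - rmax - 1)):min(h, ceiling(cy + rmax + 1))
  xs <- max(1L, floor(cx - rmax - 1)):min(w, ceiling(cx + rmax + 1))
  dy <- outer(ys - cy, rep(1, length(xs)))
  dx <- outer(rep(1, length(ys)), xs - cx)
  dist <- sqrt(dy^2 + dx^2)
  theta <- atan2(dy, dx)
  rtheta <- r0 * (1 + irregularity * sin(lobes * theta + phase))
  list(ys = ys, xs = xs, inside = dist <= rtheta)
}

# linear pixel indices of a blob footprint inside the full image
blob_lin_idx <- function(bm, h) {
  lin <- outer(bm$ys, (bm$xs - 1L) * h, `+`)
  lin[bm$inside]
}

paint_blob <- function(planes, lin, color, alpha) {
  for (ch in 1:3) {
    planes[[ch]][lin] <- (1 - alpha) * planes[[ch]][lin] + alpha * color[ch]
  }
  planes
}

#' Generate one synthetic labeled patch
#'
#' Deterministic for a fixed `(label, params, seed)` triple. Benign patches
#' have an all-zero ground-truth mask; malignant patches carry the exact
#' binary footprint of the planted blob clusters (after morphological closing
#' with a 2-pixel square element).
#'
#' @param label `"benign"`/`0` or `"malignant"`/`1`.
#' @param params a [generator_params()] object.
#' @param seed integer seed.
#' @return a `labeled_image` with fields `pixels` (HxWx3 array in \[0,1\]),
#'   `label` (0/1), `gt_mask` (HxW 0/1 matrix) and `patient_id`.
#' @export
generate_image <- function(label, params = generator_params(), seed = 1L) {
  if (!inherits(params, "generator_params")) params <- do.call(generator_params, params)
  lab <- if (is.character(label)) match(label, c("benign", "malignant")) - 1L
         else as.integer(label)
  if (is.na(lab) || !lab %in% c(0L, 1L)) stop_config("label must be benign/malignant (0/1)")
  h <- params$height; w <- params$width
  with_seed(seed, {
    planes <- lapply(1:3, function(ch) {
      matrix(params$background[ch] + rnorm(h * w, 0, params$noise_sd), h, w)
    })
    # sparse regular low-contrast blobs in both classes (benign tissue texture)
    bn <- params$benign
    n_blobs <- sample(bn$n_blobs[1]:bn$n_blobs[2], 1)
    for (i in seq_len(n_blobs)) {
      bm <- blob_mask(h, w,
                      cy = runif(1, 1, h), cx = runif(1, 1, w),
                      r0 = runif(1, bn$radius[1], bn$radius[2]) * h,
                      irregularity = bn$irregularity,
                      lobes = sample(3:6, 1), phase = runif(1, 0, 2 * pi))
      planes <- paint_blob(planes, blob_lin_idx(bm, h), bn$color, bn$alpha)
    }
    gt <- matrix(FALSE, h, w)
    if (lab == 1L) {
      mg <- params$malignant
      n_clusters <- sample(mg$n_clusters[1]:mg$n_clusters[2], 1)
      for (k in seq_len(n_clusters)) {
        crad <- runif(1, mg$cluster_radius[1], mg$cluster_radius[2]) * h
        ccy <- runif(1, crad, h - crad); ccx <- runif(1, crad, w - crad)
        n_b <- sample(mg$blobs_per_cluster[1]:mg$blobs_per_cluster[2], 1)
        for (i in seq_len(n_b)) {
          bm <- blob_mask(h, w,
                          cy = min(max(ccy + rnorm(1, 0, crad / 2), 1), h),
                          cx = min(max(ccx + rnorm(1, 0, crad / 2), 1), w),
                          r0 = runif(1, mg$blob_radius[1], mg$blob_radius[2]) * h,
                          irregularity = mg$irregularity,
                          lobes = sample(3:7, 1), phase = runif(1, 0, 2 * pi))
          lin <- blob_lin_idx(bm, h)
          planes <- paint_blob(planes, lin, mg$color, mg$alpha)
          gt[lin] <- TRUE
        }
      }
      gt <- close_mask(gt, r = 2L)
    }
    pixels <- clamp01(array(c(planes[[1]], planes[[2]], planes[[3]]),
                            dim = c(h, w, 3)))
    new_labeled_image(pixels, lab, matrix(as.integer(gt), h, w))
  })
}

#' Mean grey intensity of an image region
#'
#' @param image a `labeled_image` or HxWx3 array.
#' @param mask optional HxW 0/1 matrix restricting the region.
#' @return scalar mean of the channel-averaged intensity over the region.
#' @export
region_intensity <- function(image, mask = NULL) {
  px <- if (inherits(image, "labeled_image")) image$pixels else image
  grey <- (px[, , 1] + px[, , 2] + px[, , 3]) / 3
  if (is.null(mask)) mean(grey) else mean(grey[mask > 0])
}
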