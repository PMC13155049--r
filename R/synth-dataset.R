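# apportion n into parts proportional to fractions, exactly (largest remainder)
apportion <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    order_by_frac <- order(raw - base, decreasing = TRUE)
    base[order_by_frac[seq_len(rem)]] <- base[order_by_frac[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Generate a patient-wise stratified synthetic dataset
#'
#' Images are grouped into synthetic "patients" of `images_per_patient`
#' consecutive images; patients (never individual images) are assigned to the
#' train/validation/test partitions, so no patient's images leak across
#' partitions. Partition sizes follow `fractions` exactly when every patient
#' contributes a single image, and to within one patient group otherwise.
#' Class balance is preserved because patients are single-class and each class
#' is apportioned independently.
#'
#' @param n_per_class images per class.
#' @param fractions length-3 train/val/test fractions summing to 1.
#' @param images_per_patient images grouped under one patient identifier.
#' @param seed integer seed; fixed seeds give bit-identical datasets.
#' @param params a [generator_params()] object used for every image.
#' @return a `dataset_split`: list with `train`, `val`, `test` lists of
#'   `labeled_image` objects.
#' @export
generate_dataset <- function(n_per_class, fractions = c(0.8, 0.1, 0.1),
                             images_per_patient = 1L, seed = 1L,
                             params = generator_params()) {
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-8) {
    stop_config("fractions must be three values summing to 1")
  }
  if (n_per_class < 1 || images_per_patient < 1) {
    stop_config("n_per_class and images_per_patient must be positive")
  }
  split_names <- c("train", "val", "test")
  out <- list(train = list(), val = list(), test = list())
  for (class_idx in 0:1) {
    class_name <- c("benign", "malignant")[class_idx + 1]
    n_patients <- ceiling(n_per_class / images_per_patient)
    sizes <- rep(images_per_patient, n_patients)
    sizes[n_patients] <- n_per_class - images_per_patient * (n_patients - 1)
    patient_ids <- sprintf("P%04d_%s", seq_len(n_patients), class_name)
    perm <- with_seed(derive_seed(seed, 100 + class_idx), sample(n_patients))
    counts <- apportion(n_patients, fractions)
    assignment <- rep(split_names, counts)[order(perm)]
    img_counter <- 0L
    for (p in seq_len(n_patients)) {
      for (j in seq_len(sizes[p])) {
        img_counter <- img_counter + 1L
        img <- generate_image(class_idx, params,
                              seed = derive_seed(seed, 1000 + class_idx * 500000 + img_counter))
        img$patient_id <- patient_ids[p]
        out[[assignment[p]]] <- c(out[[assignment[p]]], list(img))
      }
    }
  }
  structure(out, class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  for (s in names(x)) {
    labs <- vapply(x[[s]], function(i) i$label, integer(1))
    cat(sprintf("%-5s: %d images (%d benign / %d malignant)\n",
                s, length(labs), sum(labs == 0), sum(labs == 1)))
  }
  invisible(x)
}

#' Augmentation configuration
#'
#' @param rotate allow random quarter-turn rotations (-90, 0, +90 degrees).
#' @param hflip,vflip allow random horizontal / vertical flips.
#' @param jitter allow photometric color jitter.
#' @param brightness maximum additive brightness shift.
#' @param contrast maximum relative contrast change.
#' @return an `augment_config` list. With all switches off, [augment()] is the
#'   identity.
#' @export
augment_config <- function(rotate = TRUE, hflip = TRUE, vflip = TRUE,
                           jitter = TRUE, brightness = 0.1, contrast = 0.1) {
  structure(list(rotate = rotate, hflip = hflip, vflip = vflip, jitter = jitter,
                 brightness = brightness, contrast = contrast),
            class = "augment_config")
}

#' Flip an image (and its mask) along one axis
#' @param image a `labeled_image`.
#' @param axis `"h"` (left-right) or `"v"` (up-down).
#' @export
flip_image <- function(image, axis = c("h", "v")) {
  axis <- match.arg(axis)
  px <- image$pixels
  if (axis == "h") {
    image$pixels <- px[, ncol(image$gt_mask):1, , drop = FALSE]
    image$gt_mask <- image$gt_mask[, ncol(image$gt_mask):1, drop = FALSE]
  } else {
    image$pixels <- px[nrow(image$gt_mask):1, , , drop = FALSE]
    image$gt_mask <- image$gt_mask[nrow(image$gt_mask):1, , drop = FALSE]
  }
  image
}

#' Rotate an image (and its mask) by quarter turns
#' @param image a `labeled_image`.
#' @param quarter_turns integer; +1 is a 90-degree counter-clockwise turn.
#' @export
rotate_image <- function(image, quarter_turns = 1L) {
  k <- ((quarter_turns %% 4) + 4) %% 4
  rot90 <- function(m) t(m)[ncol(m):1, , drop = FALSE]  # one CCW turn
  for (i in seq_len(k)) {
    image$gt_mask <- rot90(image$gt_mask)
    image$pixels <- {
      px <- image$pixels
      array(c(rot90(px[, , 1]), rot90(px[, , 2]), rot90(px[, , 3])),
            dim = c(dim(px)[2], dim(px)[1], 3))
    }
  }
  image
}

#' Randomly augment a labeled image
#'
#' Applies (per the training recipe) random quarter-turn rotations, horizontal
#' and vertical flips, and photometric color jitter. Geometric transforms are
#' co-applied to the ground-truth mask; jitter is clipped back to \[0,1\].
#' Deterministic per seed.
#'
#' @param image a `labeled_image`.
#' @param seed integer seed.
#' @param config an [augment_config()].
#' @return the augmented `labeled_image`.
#' @export
augment <- function(image, seed = 1L, config = augment_config()) {
  with_seed(seed, {
    if (isTRUE(config$rotate)) {
      k <- sample(c(-1L, 0L, 1L), 1)
      if (k != 0L) image <- rotate_image(image, k)
    }
    if (isTRUE(config$hflip) && runif(1) < 0.5) image <- flip_image(image, "h")
    if (isTRUE(config$vflip) && runif(1) < 0.5) image <- flip_image(image, "v")
    if (isTRUE(config$jitter)) {
      b <- runif(1, -config$brightness, config$brightness)
      cfac <- 1 + runif(1, -config$contrast, config$contrast)
      px <- image$pixels
      image$pixels <- clamp01((px - 0.5) * cfac + 0.5 + b)
    }
    image
  })
}

#' Standardize an image collection to zero mean and unit variance per channel
#'
#' When `stats` is omitted the per-channel mean and standard deviation are
#' computed over all pixels of the collection itself (the training partition,
#' in the standard leakage-free convention) and attached to the result as
#' attribute `"stats"`, so validation/test collections can be standardized
#' with training statistics.
#'
#' @param images list of `labeled_image` objects (or HxWx3 arrays).
#' @param stats optional `list(mean = , sd = )` of length-3 channel vectors.
#' @return the collection with standardized pixels; attribute `"stats"` holds
#'   the statistics used.
#' @export
normalize_images <- function(images, stats = NULL) {
  if (length(images) == 0) stop_config("empty image collection")
  get_px <- function(im) if (inherits(im, "labeled_image")) im$pixels else im
  if (is.null(stats)) {
    ch_vals <- lapply(1:3, function(ch) {
      unlist(lapply(images, function(im) as.vector(get_px(im)[, , ch])))
    })
    mu <- vapply(ch_vals, mean, numeric(1))
    # population SD: the collection standardizes exactly to unit variance
    sdev <- vapply(ch_vals, function(v) sqrt(mean((v - mean(v))^2)), numeric(1))
    zero <- which(sdev <= .Machine$double.eps)
    if (length(zero)) {
      stop_config("zero-variance channel(s): ",
                  paste(c("R", "G", "B")[zero], collapse = ", "))
    }
    stats <- list(mean = mu, sd = sdev)
  }
  if (any(stats$sd <= 0)) stop_config("channel standard deviations must be > 0")
  out <- lapply(images, function(im) {
    px <- get_px(im)
    for (ch in 1:3) px[, , ch] <- (px[, , ch] - stats$mean[ch]) / stats$sd[ch]
    if (inherits(im, "labeled_image")) { im$pixels <- px; im } else px
  })
  attr(out, "stats") <- stats
  out
}

#' Write a dataset split to disk
#'
#' Layout: `root/{train,val,test}/{benign,malignant}/img_XXXX.png`, with a
#' sibling `img_XXXX_mask.png` (8-bit 0/255) for malignant images, and a
#' `manifest.csv` with columns image_path, label, patient_id, split.
#'
#' @param split a `dataset_split`.
#' @param dir output directory.
#' @param force overwrite an existing non-empty directory.
#' @return (invisibly) the manifest data frame.
#' @export
write_dataset <- function(split, dir, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force) {
    stop_config("output directory ", dir, " is non-empty; use force = TRUE")
  }
  rows <- list()
  counter <- 0L
  for (s in c("train", "val", "test")) {
    for (img in split[[s]]) {
      counter <- counter + 1L
      cls <- c("benign", "malignant")[img$label + 1]
      subdir <- file.path(dir, s, cls)
      dir.create(subdir, recursive = TRUE, showWarnings = FALSE)
      rel <- file.path(s, cls, sprintf("img_%04d.png", counter))
      png::writePNG(img$pixels, file.path(dir, rel))
      if (img$label == 1L) {
        png::writePNG(img$gt_mask + 0,   # 0/1 integer -> real for 8-bit PNG
                      file.path(dir, s, cls, sprintf("img_%04d_mask.png", counter)))
      }
      rows[[length(rows) + 1]] <- data.frame(
        image_path = rel, label = img$label,
        patient_id = img$patient_id, split = s, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Load a dataset split written by [write_dataset()]
#' @param dir dataset root containing `manifest.csv`.
#' @return a `dataset_split`.
#' @export
load_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stop_config("no manifest.csv under ", dir)
  manifest <- read.csv(mf, stringsAsFactors = FALSE)
  out <- list(train = list(), val = list(), test = list())
  for (i in seq_len(nrow(manifest))) {
    px <- png::readPNG(file.path(dir, manifest$image_path[i]))
    if (length(dim(px)) == 2) px <- array(rep(px, 3), dim = c(dim(px), 3))
    px <- px[, , 1:3, drop = FALSE]
    mask_path <- sub("\\.png$", "_mask.png", file.path(dir, manifest$image_path[i]))
    gt <- if (file.exists(mask_path)) {
      m <- png::readPNG(mask_path)
      if (length(dim(m)) == 3) m <- m[, , 1]
      matrix(as.integer(m > 0.5), nrow(m), ncol(m))
    } else matrix(0L, dim(px)[1], dim(px)[2])
    img <- new_labeled_image(px, manifest$label[i], gt, manifest$patient_id[i])
    out[[manifest$split[i]]] <- c(out[[manifest$split[i]]], list(img))
  }
  structure(out, class = "dataset_split")
}
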