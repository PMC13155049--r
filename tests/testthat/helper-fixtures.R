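# Shared fixtures. Expensive objects (the desk-scale trained model) are built
# once per test run and memoized here.

.fixture_env <- new.env(parent = emptyenv())

small_params <- function() generator_params(32L, 32L)

# a rectangular tiling as a superpixel map with an exact region count
tile_segmentation <- function(h, w, rows, cols) {
  labels <- matrix(0L, h, w)
  rh <- h %/% rows; cw <- w %/% cols
  for (r in 0:(rows - 1)) for (cc in 0:(cols - 1)) {
    ys <- (r * rh + 1):(if (r == rows - 1) h else (r + 1) * rh)
    xs <- (cc * cw + 1):(if (cc == cols - 1) w else (cc + 1) * cw)
    labels[ys, xs] <- r * cols + cc
  }
  structure(list(labels = labels, k = rows * cols), class = "superpixel_map")
}

# the desk-scale experiment: 200/50/50 synthetic 64x64 patches, small
# dual-branch model trained from scratch with the from-scratch learning-rate
# range; memoized because several interpretability tests reuse it
desk_scale_fit <- function() {
  if (!is.null(.fixture_env$fit)) return(.fixture_env$fit)
  data <- generate_dataset(150, c(200 / 300, 50 / 300, 50 / 300),
                           images_per_patient = 1L, seed = 11)
  model <- build_model(tiny_backbone(c(8L, 16L, 32L)),
                       tiny_backbone(c(12L, 24L, 32L)), seed = 5)
  cfg <- train_config(lr_high = 5e-3, lr_low = 5e-4, max_epochs = 10L,
                      patience = 5L, seed = 5)
  fit <- train_model(model, data, cfg)
  fit$data <- data
  .fixture_env$fit <- fit
  fit
}

# 50 held-out malignant images for saliency evaluation, memoized
malignant_eval_set <- function(n = 50) {
  key <- paste0("mal", n)
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  imgs <- lapply(seq_len(n), function(i) {
    generate_image(1L, generator_params(), seed = derive_seed(99, i))
  })
  .fixture_env[[key]] <- imgs
  imgs
}

# simple deterministic nonlinear image score used as a cheap model_fn
toy_image_score <- function(imgs) {
  vapply(imgs, function(x) {
    p <- if (inherits(x, "labeled_image")) x$pixels else x
    tanh(3 * mean(p[, , 1]^2) - 2 * mean(p[, , 2]) + mean(p[, , 3]^3))
  }, numeric(1))
}
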