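test_that("superpixel segmentation partitions the image into compact regions", {
  uniform <- array(0.5, dim = c(32, 32, 3))
  seg <- segment_superpixels(uniform, 4)
  expect_identical(seg$k, 4L)
  sizes <- as.vector(table(seg$labels))
  expect_true(all(abs(sizes - 256) <= 26))  # near-equal tiles (within 10%)

  im <- generate_image(1, generator_params(), seed = 3)
  seg50 <- segment_superpixels(im, 50)
  expect_true(seg50$k >= 25 && seg50$k <= 100)
  expect_setequal(unique(as.vector(seg50$labels)), 0:(seg50$k - 1))
  expect_identical(segment_superpixels(im, 50)$labels, seg50$labels)

  expect_error(segment_superpixels(uniform, 1), class = "cramnet_config_error")
  expect_error(segment_superpixels(uniform, 5000), class = "cramnet_config_error")
})

test_that("masking replaces exactly the absent superpixels with the mean color", {
  im <- generate_image(1, small_params(), seed = 5)
  seg <- segment_superpixels(im, 9)
  full <- mask_superpixels(im$pixels, seg, 0:(seg$k - 1))
  expect_identical(full, im$pixels)

  empty <- mask_superpixels(im$pixels, seg, integer(0))
  for (ch in 1:3) {
    expect_true(all(abs(empty[, , ch] - mean(im$pixels[, , ch])) < 1e-12))
  }

  keep <- setdiff(0:(seg$k - 1), 0L)
  one_absent <- mask_superpixels(im$pixels, seg, keep)
  changed <- which(apply(abs(one_absent - im$pixels), c(1, 2), sum) > 0)
  region <- which(seg$labels == 0L)
  expect_true(all(changed %in% region))

  expect_error(mask_superpixels(im$pixels, seg, c(0L, seg$k)),
               class = "cramnet_validation_error")
})

test_that("exact Shapley values satisfy the dummy, symmetry and efficiency axioms", {
  im <- generate_image(1, small_params(), seed = 6)
  seg <- tile_segmentation(32, 32, 2, 3)

  constant_fn <- function(imgs) rep(1.7, length(imgs))
  sv <- exact_shapley(constant_fn, im, seg)
  expect_equal(max(abs(sv$phi)), 0)
  expect_equal(sv$base_value + sum(sv$phi), sv$value_full, tolerance = 1e-10)

  # value additive in per-region mean intensity: phi_i is exactly region i's
  # own term (mean intensity present vs mean-masked)
  region_means <- vapply(0:(seg$k - 1), function(r) {
    mean(im$pixels[, , 1][seg$labels == r])
  }, numeric(1))
  sizes <- as.vector(table(seg$labels))
  additive_fn <- function(imgs) {
    vapply(imgs, function(x) {
      p <- if (inherits(x, "labeled_image")) x$pixels else x
      sum(vapply(0:(seg$k - 1), function(r) mean(p[, , 1][seg$labels == r]),
                 numeric(1)))
    }, numeric(1))
  }
  sv_add <- exact_shapley(additive_fn, im, seg)
  masked_mean <- mean(im$pixels[, , 1])
  expect_equal(sv_add$phi, region_means - masked_mean, tolerance = 1e-10)

  # symmetry: two regions engineered to contribute identically
  sym_fn <- function(imgs) {
    vapply(imgs, function(x) {
      p <- if (inherits(x, "labeled_image")) x$pixels else x
      present <- vapply(0:(seg$k - 1), function(r) {
        any(abs(p[, , 1][seg$labels == r] - im$pixels[, , 1][seg$labels == r]) < 1e-12)
      }, logical(1))
      as.numeric(present[1] || present[2]) + 0.3 * sum(present)
    }, numeric(1))
  }
  sv_sym <- exact_shapley(sym_fn, im, seg)
  expect_equal(sv_sym$phi[1], sv_sym$phi[2], tolerance = 1e-10)

  big <- structure(list(labels = matrix(0L, 64, 64), k = 13L),
                   class = "superpixel_map")
  expect_error(exact_shapley(constant_fn, im, big), "kernel_shap")
})

test_that("exact Shapley is linear in the value function", {
  im <- generate_image(0, small_params(), seed = 7)
  seg <- tile_segmentation(32, 32, 2, 2)
  f1 <- function(imgs) toy_image_score(imgs)
  f2 <- function(imgs) vapply(imgs, function(x) {
    p <- if (inherits(x, "labeled_image")) x$pixels else x
    mean(p)^2
  }, numeric(1))
  fsum <- function(imgs) f1(imgs) + 2 * f2(imgs)
  s1 <- exact_shapley(f1, im, seg)
  s2 <- exact_shapley(f2, im, seg)
  s12 <- exact_shapley(fsum, im, seg)
  expect_equal(s12$phi, s1$phi + 2 * s2$phi, tolerance = 1e-10)
})

test_that("kernel SHAP reproduces the exact oracle under full enumeration", {
  im <- generate_image(1, generator_params(), seed = 3)
  seg8 <- tile_segmentation(64, 64, 4, 2)
  ex <- exact_shapley(toy_image_score, im, seg8)
  ks <- kernel_shap(toy_image_score, im, seg8, n_samples = 254, seed = 1)
  expect_lt(max(abs(ks$phi - ex$phi)), 1e-6)
  expect_lt(abs(ks$base_value + sum(ks$phi) - ks$value_full), 1e-8)

  # sampled regime: efficiency still exact, deterministic per seed
  seg <- segment_superpixels(im, 30)
  ks1 <- kernel_shap(toy_image_score, im, seg, n_samples = 120, seed = 4)
  ks2 <- kernel_shap(toy_image_score, im, seg, n_samples = 120, seed = 4)
  expect_identical(ks1$phi, ks2$phi)
  expect_lt(abs(ks1$base_value + sum(ks1$phi) - ks1$value_full), 1e-8)

  constant_fn <- function(imgs) rep(0.2, length(imgs))
  k0 <- kernel_shap(constant_fn, im, seg8, n_samples = 254, seed = 1)
  expect_equal(max(abs(k0$phi)), 0, tolerance = 1e-10)
  expect_error(kernel_shap(toy_image_score, im, seg8, n_samples = 5),
               class = "cramnet_config_error")
})

test_that("attribution overlays use a symmetric diverging scale", {
  im <- generate_image(1, small_params(), seed = 9)
  seg <- tile_segmentation(32, 32, 2, 2)
  neutral <- shap_overlay(im, seg, rep(0, 4))
  expect_true(all(neutral == 1))

  phi <- c(0.8, -0.4, 0.1, -0.05)
  ov <- shap_overlay(im, seg, phi)
  ov_flip <- shap_overlay(im, seg, -phi)
  expect_equal(ov[, , 1], ov_flip[, , 3])
  expect_equal(ov[, , 3], ov_flip[, , 1])
  expect_equal(ov[, , 2], ov_flip[, , 2])
  # the most positive region is the reddest (highest R - B difference)
  redness <- vapply(0:3, function(r) {
    sel <- seg$labels == r
    mean(ov[, , 1][sel] - ov[, , 3][sel])
  }, numeric(1))
  expect_identical(which.max(redness), which.max(phi))
  expect_error(shap_overlay(im, seg, rep(0, 5)), class = "cramnet_validation_error")
})

test_that("on the trained model, planted regions carry positive attribution mass", {
  fit <- desk_scale_fit()
  mal <- malignant_eval_set(15)
  pred <- classify(predict(fit$model, mal))
  correct <- which(pred == 1L)
  pfun <- as_predictor(fit$model)
  positive <- vapply(correct, function(i) {
    im <- mal[[i]]
    seg <- segment_superpixels(im, 50)
    sv <- kernel_shap(pfun, im, seg, n_samples = 300, seed = i)
    touching <- unique(seg$labels[im$gt_mask > 0])
    sum(sv$phi[touching + 1]) > 0
  }, logical(1))
  expect_gte(mean(positive), 0.9)
})
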