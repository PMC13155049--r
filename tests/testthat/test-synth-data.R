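test_that("benign patches carry no planted region and generation is seeded", {
  p <- small_params()
  b <- generate_image("benign", p, seed = 1)
  expect_s3_class(b, "labeled_image")
  expect_identical(sum(b$gt_mask), 0L)
  expect_true(all(b$pixels >= 0 & b$pixels <= 1))

  m1 <- generate_image("malignant", p, seed = 1)
  m2 <- generate_image("malignant", p, seed = 1)
  expect_identical(m1$pixels, m2$pixels)
  expect_identical(m1$gt_mask, m2$gt_mask)
  expect_false(identical(m1$pixels, generate_image("malignant", p, seed = 2)$pixels))
  expect_gt(sum(m1$gt_mask), 0)
})

test_that("planted regions are darker than background by more than the contrast setting", {
  for (seed in c(7, 21, 42)) {
    im <- generate_image("malignant", generator_params(), seed = seed)
    inside <- region_intensity(im, im$gt_mask)
    outside <- region_intensity(im, 1 - im$gt_mask)
    expect_gt(outside - inside, generator_params()$contrast)
  }
})

test_that("generator rejects invalid sizes and degenerate ranges", {
  expect_error(generator_params(16, 16), class = "cramnet_config_error")
  expect_error(generator_params(benign = list(n_blobs = c(10, 5), radius = c(0.03, 0.06),
                                              irregularity = 0, color = rep(0.5, 3), alpha = 0.5)),
               class = "cramnet_config_error")
  expect_error(generate_image("ductal", small_params()), class = "cramnet_config_error")
})

test_that("splits honor the requested fractions exactly for unit patient groups", {
  split <- generate_dataset(10, c(0.8, 0.1, 0.1), 1, seed = 3, params = small_params())
  expect_length(split$train, 16)
  expect_length(split$val, 2)
  expect_length(split$test, 2)
  # class balance per partition
  for (s in c("train", "val", "test")) {
    labs <- vapply(split[[s]], function(i) i$label, integer(1))
    expect_equal(sum(labs == 0), sum(labs == 1))
  }
  expect_error(generate_dataset(10, c(0.8, 0.1, 0.2), 1), class = "cramnet_config_error")
})

test_that("no patient identifier crosses partitions", {
  split <- generate_dataset(10, c(0.8, 0.1, 0.1), images_per_patient = 5,
                            seed = 9, params = small_params())
  ids <- lapply(split, function(part) unique(vapply(part, function(i) i$patient_id,
                                                    character(1))))
  expect_length(intersect(ids$train, ids$val), 0)
  expect_length(intersect(ids$train, ids$test), 0)
  expect_length(intersect(ids$val, ids$test), 0)
  # every image of a patient stays together
  all_ids <- unlist(lapply(split, function(part) vapply(part, function(i) i$patient_id,
                                                        character(1))))
  expect_equal(sum(table(all_ids) == 5), 4)  # 4 patients of 5 images (2 per class)
})

test_that("identical seeds give bit-identical datasets", {
  a <- generate_dataset(4, c(0.5, 0.25, 0.25), 1, seed = 5, params = small_params())
  b <- generate_dataset(4, c(0.5, 0.25, 0.25), 1, seed = 5, params = small_params())
  expect_identical(a, b)
})

test_that("augmentation preserves labels and co-transforms the mask", {
  im <- generate_image(1, small_params(), seed = 4)
  idcfg <- augment_config(rotate = FALSE, hflip = FALSE, vflip = FALSE, jitter = FALSE)
  expect_identical(augment(im, 1, idcfg), im)

  expect_identical(flip_image(flip_image(im, "h"), "h"), im)
  expect_identical(flip_image(flip_image(im, "v"), "v"), im)

  rot <- rotate_image(im, 1)
  expect_identical(sum(rot$gt_mask), sum(im$gt_mask))
  expect_identical(rotate_image(rot, 3), im)

  aug <- augment(im, seed = 8)
  expect_identical(aug$label, im$label)
  expect_true(all(aug$pixels >= 0 & aug$pixels <= 1))
  expect_identical(sum(aug$gt_mask), sum(im$gt_mask))
  expect_identical(augment(im, seed = 8), aug)
})

test_that("standardization reaches zero mean unit variance and flags flat channels", {
  imgs <- lapply(1:4, function(i) generate_image(i %% 2, small_params(), seed = i))
  norm <- normalize_images(lapply(imgs, function(i) i$pixels))
  for (ch in 1:3) {
    vals <- unlist(lapply(norm, function(p) p[, , ch]))
    expect_lt(abs(mean(vals)), 1e-6)
    expect_lt(abs(mean(vals^2) - 1), 1e-6)
  }
  # hand-computable two-image toy set: channel values {0, 1} -> {-1, +1}
  a <- array(0, dim = c(32, 32, 3)); b <- array(1, dim = c(32, 32, 3))
  toy <- normalize_images(list(a, b))
  expect_equal(unique(as.vector(toy[[1]])), -1)
  expect_equal(unique(as.vector(toy[[2]])), 1)
  # stats reuse: same transformation applied to new data
  c2 <- normalize_images(list(array(0.75, dim = c(32, 32, 3))),
                         stats = attr(toy, "stats"))
  expect_equal(unique(as.vector(c2[[1]])), 0.5)

  expect_error(normalize_images(list(a, a)), class = "cramnet_config_error")
  expect_error(normalize_images(list(a, a)), "R, G, B")
})

test_that("the two classes are linearly separable from simple image features", {
  imgs <- lapply(1:200, function(i) generate_image(i %% 2, generator_params(),
                                                   seed = derive_seed(1234, i)))
  labs <- vapply(imgs, function(i) i$label, integer(1))
  feats <- t(vapply(imgs, function(im) {
    grey <- (im$pixels[, , 1] + im$pixels[, , 2] + im$pixels[, , 3]) / 3
    c(mean_intensity = mean(grey), dark_frac = mean(grey < 0.6))
  }, numeric(2)))
  fit <- suppressWarnings(stats::glm(labs ~ feats, family = stats::binomial()))
  acc <- mean((stats::fitted(fit) >= 0.5) == (labs == 1))
  expect_gt(acc, 0.95)
})

test_that("datasets round-trip through the on-disk layout", {
  dir <- withr::local_tempdir()
  split <- generate_dataset(4, c(0.5, 0.25, 0.25), 1, seed = 2, params = small_params())
  manifest <- write_dataset(split, dir)
  expect_identical(nrow(manifest), 8L)
  expect_setequal(unique(manifest$split), c("train", "val", "test"))
  expect_error(write_dataset(split, dir), class = "cramnet_config_error")

  back <- load_dataset(dir)
  expect_length(back$train, length(split$train))
  orig_labels <- vapply(split$train, function(i) i$label, integer(1))
  back_labels <- vapply(back$train, function(i) i$label, integer(1))
  expect_identical(sort(orig_labels), sort(back_labels))
  # PNG round trip is 8-bit; pixels agree to quantization precision
  expect_lt(max(abs(back$train[[1]]$pixels - split$train[[1]]$pixels)), 1 / 255)
  mal <- Filter(function(i) i$label == 1L, back$test)
  if (length(mal)) expect_true(all(vapply(mal, function(i) sum(i$gt_mask) > 0, logical(1))))
})
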