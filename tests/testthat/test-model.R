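test_that("dual-branch plumbing: fused width, valid forward, normalized probabilities", {
  m <- build_model(tiny_backbone(c(4L, 6L, 8L)), tiny_backbone(c(4L, 4L, 6L)), seed = 1)
  expect_identical(m$feature_length, 14L)
  img <- withr::with_seed(1, array(stats::runif(64 * 64 * 3), dim = c(64, 64, 3)))
  out <- model_forward(m, img)
  expect_length(out$probs, 2)
  expect_true(all(out$probs >= 0))
  expect_equal(sum(out$probs), 1, tolerance = 1e-6)
  expect_length(out$fused, 14)
  expect_length(out$a1, 14)
  expect_length(out$a2, 14)
  expect_true(all(out$a1 > 0 & out$a1 < 1))
})

test_that("forward is deterministic and batch rows are independent", {
  m <- build_model(seed = 2)
  img <- withr::with_seed(2, array(stats::runif(32 * 32 * 3), dim = c(32, 32, 3)))
  img2 <- withr::with_seed(3, array(stats::runif(32 * 32 * 3), dim = c(32, 32, 3)))
  fw <- cramnet:::model_batch_forward(m, list(img, img2, img), train = FALSE)
  expect_equal(fw$probs[1, ], fw$probs[3, ])
  single <- model_forward(m, img)
  expect_equal(drop(fw$probs[1, ]), single$probs)
  # softmax shift invariance: moving both head biases by a constant
  m2 <- m
  m2$params$head.b <- m$params$head.b + 3.7
  expect_equal(model_forward(m2, img)$probs, single$probs, tolerance = 1e-12)
})

test_that("input validation catches wrong channel counts and spatial sizes", {
  m <- build_model(seed = 1)
  expect_error(model_forward(m, array(0.5, dim = c(32, 32, 4))),
               class = "cramnet_validation_error")
  expect_error(model_forward(m, array(0.5, dim = c(30, 30, 3))),
               class = "cramnet_validation_error")
})

test_that("plain fusion and zero-gate attention differ exactly by the head response to Z'", {
  base <- build_model(attention_mode = "none", seed = 4)
  withcram <- build_model(attention_mode = "cram", seed = 4)
  # share every common parameter; zero the gating weights so A = 0.5 exactly
  for (nm in names(base$params)) withcram$params[[nm]] <- base$params[[nm]]
  for (nm in grep("^cram\\..*\\.(W1|W2)$", names(withcram$params), value = TRUE)) {
    withcram$params[[nm]][] <- 0
  }
  img <- withr::with_seed(5, array(stats::runif(32 * 32 * 3), dim = c(32, 32, 3)))
  out_none <- model_forward(base, img)
  out_cram <- model_forward(withcram, img)
  x <- out_none$fused
  zprime <- pmax(0.5 * pmax(0.5 * x, 0), 0)      # closed form at neutral gates
  expected_delta <- as.vector(zprime %*% base$params$head.W)
  expect_equal(out_cram$logits - out_none$logits, expected_delta, tolerance = 1e-10)
})

test_that("scores live in [0,1], duplicates agree, and 0.5 classifies malignant", {
  m <- build_model(seed = 6)
  imgs <- lapply(1:4, function(i) generate_image(i %% 2, small_params(), seed = i))
  sc <- predict(m, c(imgs, imgs[1]))
  expect_true(all(sc >= 0 & sc <= 1))
  expect_equal(sc[1], sc[5])
  expect_identical(classify(c(0.49, 0.5, 0.51)), c(0L, 1L, 1L))
})

test_that("early stopping fires after `patience` non-improving epochs", {
  data <- generate_dataset(8, c(0.5, 0.25, 0.25), 1, seed = 7, params = small_params())
  m <- build_model(tiny_backbone(c(2L, 2L, 4L)), tiny_backbone(c(2L, 2L, 4L)), seed = 7)
  # freeze everything: validation loss cannot improve after epoch 1
  cfg <- train_config(lr_high = 1e-3, lr_low = 1e-4, batch_size = 4, max_epochs = 10,
                      patience = 1, augment = FALSE, seed = 7,
                      freeze_schedule = list(list(epoch = 1L, unfreeze = "matches_nothing")))
  fit <- train_model(m, data, cfg)
  expect_identical(fit$history$stopping_epoch, 2L)
  expect_identical(fit$history$best_epoch, 1L)
  expect_equal(fit$history$log$val_loss[1], fit$history$log$val_loss[2])
})

test_that("training is reproducible per seed and rejects empty partitions", {
  data <- generate_dataset(10, c(0.6, 0.2, 0.2), 1, seed = 8, params = small_params())
  cfg <- train_config(lr_high = 2e-3, lr_low = 5e-4, batch_size = 4, max_epochs = 3,
                      patience = 5, seed = 9)
  run <- function() {
    m <- build_model(tiny_backbone(c(3L, 4L, 6L)), tiny_backbone(c(3L, 4L, 6L)), seed = 10)
    train_model(m, data, cfg)
  }
  f1 <- run(); f2 <- run()
  expect_identical(f1$history$log, f2$history$log)
  expect_identical(f1$model$params, f2$model$params)
  # loss decreases over the first epochs on separable data
  expect_lt(f1$history$log$train_loss[3], f1$history$log$train_loss[1])

  empty <- data; empty$val <- list()
  expect_error(train_model(build_model(seed = 1), empty), class = "cramnet_config_error")
  expect_error(train_config(lr_high = 1e-5, lr_low = 1e-4), class = "cramnet_config_error")
})

test_that("training without the attention residual still runs", {
  data <- generate_dataset(8, c(0.5, 0.25, 0.25), 1, seed = 12, params = small_params())
  m <- build_model(tiny_backbone(c(2L, 3L, 4L)), tiny_backbone(c(2L, 3L, 4L)),
                   residual = FALSE, seed = 12)
  cfg <- train_config(lr_high = 1e-3, lr_low = 5e-4, batch_size = 4, max_epochs = 2,
                      patience = 5, augment = FALSE, seed = 12)
  fit <- train_model(m, data, cfg)
  expect_identical(nrow(fit$history$log), 2L)
  expect_true(all(is.finite(fit$history$log$val_loss)))
})

test_that("gated attention does not slow convergence relative to plain fusion", {
  # paired seeded runs; epochs to 95% validation accuracy per attention mode
  p32 <- small_params()
  epochs_to_95 <- function(mode, seed) {
    data <- generate_dataset(75, c(100 / 150, 25 / 150, 25 / 150), 1,
                             seed = derive_seed(seed, 1), params = p32)
    m <- build_model(tiny_backbone(c(6L, 12L, 16L)), tiny_backbone(c(8L, 16L, 16L)),
                     attention_mode = mode, seed = derive_seed(seed, 2))
    cfg <- train_config(lr_high = 1.2e-3, lr_low = 4e-4, max_epochs = 6L,
                        patience = 6L, seed = derive_seed(seed, 3))
    fit <- train_model(m, data, cfg)
    e <- which(fit$history$log$val_acc >= 0.95)[1]
    if (is.na(e)) 7L else e
  }
  res <- vapply(1:5, function(s) {
    c(cram = epochs_to_95("cram", s),
      single = epochs_to_95("single_step", s),
      none = epochs_to_95("none", s))
  }, numeric(3))
  # sign-test style tendency at the seed level (ties allowed)
  expect_gte(sum(res["cram", ] <= res["none", ]), 3)
  expect_gte(sum(res["cram", ] <= res["single", ]), 3)
  expect_gte(sum(res["single", ] <= res["none", ]), 3)
  expect_lte(mean(res["cram", ]), mean(res["none", ]))
})
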