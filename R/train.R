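#' Training configuration
#'
#' Defaults follow the reference recipe: Adam with a cyclic learning rate
#' oscillating between `lr_high` and `lr_low` (triangular cycle with a period
#' of 4 epochs: high, mid, low, mid), batch size 16, at most 50 epochs, early
#' stopping with patience 5 on validation loss, and L2 weight decay 1e-5 on
#' the classifier head and attention weights. The backbone freeze schedule
#' trains only the attention block, head and last conv block for the first 3
#' epochs, then unfreezes everything -- the warm-up used when backbones start
#' from pretrained weights. For training the small built-in backbone from
#' scratch a higher learning-rate range (e.g. `5e-3`/`5e-4`) is appropriate.
#'
#' @param lr_high,lr_low cyclic learning-rate bounds (`lr_low < lr_high`).
#' @param batch_size mini-batch size (>= 1).
#' @param max_epochs maximum training epochs.
#' @param patience early-stopping patience in epochs (>= 1).
#' @param l2 L2 weight-decay coefficient applied to head and attention weight
#'   matrices.
#' @param freeze_schedule list of `list(epoch = , unfreeze = )` entries; from
#'   each epoch on, parameters whose names match any of the `unfreeze` regex
#'   patterns become trainable (cumulatively); `"all"` unfreezes everything.
#' @param dropout_p optional dropout before the head during training.
#' @param augment apply random augmentation to training batches (online only;
#'   validation is never augmented).
#' @param augment_cfg an [augment_config()].
#' @param min_delta minimum validation-loss improvement that resets patience.
#' @param seed integer seed controlling shuffling and augmentation.
#' @return a `train_config`.
#' @export
train_config <- function(lr_high = 1e-4, lr_low = 1e-5, batch_size = 16L,
                         max_epochs = 50L, patience = 5L, l2 = 1e-5,
                         freeze_schedule = list(
                           list(epoch = 1L, unfreeze = c("^cram\\.", "^head\\.", "conv3")),
                           list(epoch = 4L, unfreeze = "all")),
                         dropout_p = NULL, augment = TRUE,
                         augment_cfg = augment_config(),
                         min_delta = 1e-8, seed = 1L) {
  if (!(lr_low < lr_high)) stop_config("lr_low must be smaller than lr_high")
  if (patience < 1) stop_config("patience must be >= 1")
  if (batch_size < 1) stop_config("batch_size must be >= 1")
  structure(list(lr_high = lr_high, lr_low = lr_low,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), l2 = l2,
                 freeze_schedule = freeze_schedule, dropout_p = dropout_p,
                 augment = augment, augment_cfg = augment_cfg,
                 min_delta = min_delta, seed = as.integer(seed)),
            class = "train_config")
}

cyclic_lr <- function(epoch, lr_high, lr_low) {
  mid <- (lr_high + lr_low) / 2
  c(lr_high, mid, lr_low, mid)[((epoch - 1) %% 4) + 1]
}

trainable_mask <- function(param_names, freeze_schedule, epoch) {
  if (is.null(freeze_schedule)) {
    return(stats::setNames(as.list(rep(TRUE, length(param_names))), param_names))
  }
  active <- character(0)
  for (entry in freeze_schedule) {
    if (epoch >= entry$epoch) active <- c(active, entry$unfreeze)
  }
  on <- if ("all" %in% active) rep(TRUE, length(param_names)) else {
    if (length(active) == 0) rep(FALSE, length(param_names)) else
      Reduce(`|`, lapply(active, function(p) grepl(p, param_names)))
  }
  stats::setNames(as.list(on), param_names)
}

decayed_param_names <- function(model) {
  nms <- names(model$params)
  nms[grepl("^(head|cram)\\.", nms) & grepl("\\.(W|W1|W2)$", nms)]
}

eval_on <- function(model, images_norm, labels, batch_size = 64L) {
  n <- length(images_norm)
  loss_sum <- 0; correct <- 0
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    fw <- model_batch_forward(model, images_norm[i:j], train = FALSE)
    ce <- softmax_ce(fw$logits, labels[i:j])
    loss_sum <- loss_sum + ce$loss * (j - i + 1L)
    correct <- correct + sum(max.col(fw$probs) - 1L == labels[i:j])
    i <- j + 1L
  }
  list(loss = loss_sum / n, acc = correct / n)
}

#' Train the dual-branch attention classifier
#'
#' Adam optimization of 2-class cross-entropy (the softmax formulation of
#' binary cross-entropy) with L2 decay on head and attention weights, a
#' triangular cyclic learning rate, online augmentation of training batches,
#' progressive backbone unfreezing, and early stopping on validation loss with
#' best-weight restoration. Fully reproducible per `cfg$seed`.
#'
#' @param model a `hybrid_model` from [build_model()].
#' @param data a `dataset_split` with nonempty `train` and `val` partitions
#'   (raw \[0,1\] pixels; standardization statistics are computed from the
#'   training partition and stored in the model).
#' @param cfg a [train_config()].
#' @return list with `model` (best-validation-loss weights, normalization
#'   stats attached) and `history` (`train_history`: per-epoch log plus
#'   `stopping_epoch` and `best_epoch`).
#' @export
train_model <- function(model, data, cfg = train_config()) {
  if (length(data$train) == 0 || length(data$val) == 0) {
    stop_config("train and val partitions must be nonempty")
  }
  train_imgs <- data$train
  labels_tr <- vapply(train_imgs, function(im) im$label, integer(1))
  labels_va <- vapply(data$val, function(im) im$label, integer(1))
  norm <- normalize_images(lapply(train_imgs, function(im) im$pixels))
  stats <- attr(norm, "stats")
  model$norm_stats <- stats
  val_norm <- lapply(data$val, function(im) apply_norm(im$pixels, stats))

  opt <- adam_init(model$params)
  decay_names <- decayed_param_names(model)
  best_loss <- Inf; best_epoch <- 0L; best_params <- model$params
  bad_epochs <- 0L
  log <- NULL
  stopping_epoch <- cfg$max_epochs

  for (epoch in seq_len(cfg$max_epochs)) {
    lr <- cyclic_lr(epoch, cfg$lr_high, cfg$lr_low)
    mask <- trainable_mask(names(model$params), cfg$freeze_schedule, epoch)
    epoch_seed <- derive_seed(cfg$seed, 7000 + epoch)
    batch_stats <- with_seed(epoch_seed, {
      ord <- sample(length(train_imgs))
      loss_sum <- 0; correct <- 0
      i <- 1L
      while (i <= length(ord)) {
        j <- min(i + cfg$batch_size - 1L, length(ord))
        sel <- ord[i:j]
        batch <- lapply(seq_along(sel), function(q) {
          im <- train_imgs[[sel[q]]]
          if (isTRUE(cfg$augment)) {
            im <- augment(im, seed = sample.int(2147483646, 1), cfg$augment_cfg)
          }
          apply_norm(im$pixels, stats)
        })
        fw <- model_batch_forward(model, batch, train = TRUE)
        ce <- softmax_ce(fw$logits, labels_tr[sel])
        if (!is.finite(ce$loss)) {
          stop("non-finite training loss at epoch ", epoch,
               " (batch ", i, "-", j, "); consider lowering the learning rate")
        }
        grads <- model_batch_backward(model, fw, ce$dlogits)
        if (cfg$l2 > 0) {
          for (nm in decay_names) {
            grads[[nm]] <- grads[[nm]] + 2 * cfg$l2 * model$params[[nm]]
          }
        }
        step <- adam_step(model$params, grads, opt, lr, mask)
        model$params <- step$params
        opt <- step$state
        loss_sum <- loss_sum + ce$loss * length(sel)
        correct <- correct + sum(max.col(fw$probs) - 1L == labels_tr[sel])
        i <- j + 1L
      }
      list(loss = loss_sum / length(ord), acc = correct / length(ord))
    })
    va <- eval_on(model, val_norm, labels_va)
    log <- rbind(log, data.frame(epoch = epoch, lr = lr,
                                 train_loss = batch_stats$loss,
                                 train_acc = batch_stats$acc,
                                 val_loss = va$loss, val_acc = va$acc))
    if (va$loss < best_loss - cfg$min_delta) {
      best_loss <- va$loss; best_epoch <- epoch
      best_params <- model$params
      bad_epochs <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      if (bad_epochs >= cfg$patience) { stopping_epoch <- epoch; break }
    }
    stopping_epoch <- epoch
  }
  model$params <- best_params
  history <- structure(list(log = log, stopping_epoch = stopping_epoch,
                            best_epoch = best_epoch), class = "train_history")
  list(model = model, history = history)
}

#' @export
print.train_history <- function(x, ...) {
  cat(sprintf("trained %d epochs (best validation loss at epoch %d)\n",
              x$stopping_epoch, x$best_epoch))
  print(x$log, row.names = FALSE, digits = 4)
  invisible(x)
}
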