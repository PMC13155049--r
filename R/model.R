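# Dual-branch classifier: two convolutional feature extractors, concatenation,
# recurrent gated channel attention, and a 2-way softmax head.

#' Built-in small convolutional backbone specification
#'
#' Three 3x3 same-padded convolution blocks (ReLU, 2x2 average pooling after
#' the first two) followed by global average pooling, yielding an embedding of
#' width `widths[3]`. Small enough to train from scratch on synthetic patches
#' on one CPU; it fulfils the same contract (image in, fixed-width embedding
#' out, final convolutional activation map exposed) as large pretrained
#' backbones would.
#'
#' @param widths channel widths of the three conv blocks.
#' @return a `backbone_spec`.
#' @export
tiny_backbone <- function(widths = c(8L, 16L, 32L)) {
  if (length(widths) != 3 || any(widths < 1)) {
    stop_config("widths must be three positive channel counts")
  }
  structure(list(widths = as.integer(widths), embedding = as.integer(widths[3])),
            class = "backbone_spec")
}

init_backbone_params <- function(spec, prefix, seed) {
  w <- spec$widths
  cins <- c(3L, w[1], w[2])
  with_seed(seed, {
    params <- list()
    for (i in 1:3) {
      params[[paste0(prefix, ".conv", i, ".W")]] <-
        he_normal(c(3, 3, cins[i], w[i]), fan_in = 9 * cins[i])
      params[[paste0(prefix, ".conv", i, ".b")]] <- numeric(w[i])
    }
    params
  })
}

#' Build the dual-branch attention classifier
#'
#' Forward path: `concat(f_A, f_B)` -> attention block (per `attention_mode`)
#' -> optional dropout -> dense(2) softmax. `attention_mode = "none"` wires the
#' concatenated embedding straight to the head (the plain-fusion ablation);
#' `"single_step"` uses one gated pass (squeeze-and-excitation-style ablation);
#' `"cram"` is the full two-step recurrent gated attention.
#'
#' @param backbone_a,backbone_b `backbone_spec` objects (see [tiny_backbone()]).
#' @param attention_mode `"cram"`, `"single_step"` or `"none"`.
#' @param residual keep the identity residual in the attention block.
#' @param hidden_width hidden width of each gating transform; default is a
#'   tenth of the fused width (at least 32), keeping the attention + head
#'   parameter budget small relative to the backbones.
#' @param dropout_p optional dropout probability before the head (training
#'   only); `NULL` disables it.
#' @param seed integer seed for all weight initialization (He normal; biases 0
#'   so the gating sigmoids start neutral at 0.5).
#' @return a `hybrid_model`.
#' @export
build_model <- function(backbone_a = tiny_backbone(), backbone_b = tiny_backbone(),
                        attention_mode = c("cram", "single_step", "none"),
                        residual = TRUE, hidden_width = NULL, dropout_p = NULL,
                        seed = 1L) {
  attention_mode <- match.arg(attention_mode)
  d_a <- backbone_a$embedding; d_b <- backbone_b$embedding
  feature_length <- d_a + d_b
  if (is.null(hidden_width)) hidden_width <- max(32L, feature_length %/% 10L)
  params <- c(init_backbone_params(backbone_a, "a", derive_seed(seed, 1)),
              init_backbone_params(backbone_b, "b", derive_seed(seed, 2)))
  cram <- NULL
  if (attention_mode != "none") {
    steps <- if (attention_mode == "cram") 2L else 1L
    cram <- init_cram(feature_length, hidden_width, derive_seed(seed, 3), steps)
    for (k in seq_along(cram$steps)) {
      for (nm in c("W1", "b1", "W2", "b2")) {
        params[[paste0("cram.s", k, ".", nm)]] <- cram$steps[[k]][[nm]]
      }
    }
  }
  params[["head.W"]] <- with_seed(derive_seed(seed, 4),
                                  he_normal(c(feature_length, 2), feature_length))
  params[["head.b"]] <- numeric(2)
  structure(list(params = params,
                 backbone_a = backbone_a, backbone_b = backbone_b,
                 attention_mode = attention_mode, residual = residual,
                 hidden_width = as.integer(hidden_width),
                 feature_length = as.integer(feature_length),
                 dropout_p = dropout_p, norm_stats = NULL),
            class = "hybrid_model")
}

#' @export
print.hybrid_model <- function(x, ...) {
  cat(sprintf("hybrid_model: branches %d+%d -> fused %d, attention=%s%s, %s params\n",
              x$backbone_a$embedding, x$backbone_b$embedding, x$feature_length,
              x$attention_mode,
              if (x$residual) "" else " (no residual)",
              format(n_params(x), big.mark = ",")))
  invisible(x)
}

#' Total learnable parameter count
#' @param model a `hybrid_model`.
#' @export
n_params <- function(model) {
  sum(vapply(model$params, length, numeric(1)))
}

cram_params_view <- function(model) {
  steps_n <- if (model$attention_mode == "cram") 2L else 1L
  step_list <- lapply(seq_len(steps_n), function(k) {
    list(W1 = model$params[[paste0("cram.s", k, ".W1")]],
         b1 = model$params[[paste0("cram.s", k, ".b1")]],
         W2 = model$params[[paste0("cram.s", k, ".W2")]],
         b2 = model$params[[paste0("cram.s", k, ".b2")]])
  })
  structure(list(steps = step_list, feature_length = model$feature_length,
                 hidden_width = model$hidden_width), class = "cram_params")
}

as_pixel_array <- function(x) {
  px <- if (inherits(x, "labeled_image")) x$pixels else x
  if (length(dim(px)) != 3 || dim(px)[3] != 3) {
    stop_validation("images must be HxWx3 arrays (got dims ",
                    paste(dim(px), collapse = "x"), ")")
  }
  px
}

apply_norm <- function(px, stats) {
  if (is.null(stats)) return(px)
  for (ch in 1:3) px[, , ch] <- (px[, , ch] - stats$mean[ch]) / stats$sd[ch]
  px
}

backbone_batch_forward <- function(params, prefix, x3, h, w, n) {
  g <- function(nm) params[[paste0(prefix, nm)]]
  z1 <- relu(conv3x3_forward(x3, g(".conv1.W"), g(".conv1.b"), h, w, n))
  p1 <- avgpool2_forward(z1, h, w, n); h2 <- h %/% 2L; w2 <- w %/% 2L
  z2 <- relu(conv3x3_forward(p1, g(".conv2.W"), g(".conv2.b"), h2, w2, n))
  p2 <- avgpool2_forward(z2, h2, w2, n); h4 <- h2 %/% 2L; w4 <- w2 %/% 2L
  z3 <- relu(conv3x3_forward(p2, g(".conv3.W"), g(".conv3.b"), h4, w4, n))
  emb <- gap_forward(z3, h4, w4, n)
  list(emb = emb,
       cache = list(x3 = x3, z1 = z1, p1 = p1, z2 = z2, p2 = p2, z3 = z3,
                    h = h, w = w, n = n, h2 = h2, w2 = w2, h4 = h4, w4 = w4))
}

backbone_batch_backward <- function(demb, cache, params, prefix) {
  g <- function(nm) params[[paste0(prefix, nm)]]
  with(cache, {
    dz3 <- gap_backward(demb, h4, w4, n) * (z3 > 0)
    b3 <- conv3x3_backward(dz3, p2, g(".conv3.W"), h4, w4, n)
    dz2 <- avgpool2_backward(b3$dx, h2, w2, n, ncol(z2)) * (z2 > 0)
    b2 <- conv3x3_backward(dz2, p1, g(".conv2.W"), h2, w2, n)
    dz1 <- avgpool2_backward(b2$dx, h, w, n, ncol(z1)) * (z1 > 0)
    b1 <- conv3x3_backward(dz1, x3, g(".conv1.W"), h, w, n)
    grads <- list()
    grads[[paste0(prefix, ".conv3.W")]] <- b3$dkern
    grads[[paste0(prefix, ".conv3.b")]] <- b3$dbias
    grads[[paste0(prefix, ".conv2.W")]] <- b2$dkern
    grads[[paste0(prefix, ".conv2.b")]] <- b2$dbias
    grads[[paste0(prefix, ".conv1.W")]] <- b1$dkern
    grads[[paste0(prefix, ".conv1.b")]] <- b1$dbias
    grads
  })
}

# full-network batch forward; images: list of HxWx3 arrays (already normalized)
model_batch_forward <- function(model, images, train = FALSE) {
  h <- dim(images[[1]])[1]; w <- dim(images[[1]])[2]; n <- length(images)
  if (h %% 4 != 0 || w %% 4 != 0) {
    stop_validation("image spatial size must be divisible by 4, got ", h, "x", w)
  }
  x3 <- batch_to_matrix(images)
  check_finite(x3, "image batch")
  fa <- backbone_batch_forward(model$params, "a", x3, h, w, n)
  fb <- backbone_batch_forward(model$params, "b", x3, h, w, n)
  fused <- cbind(fa$emb, fb$emb)
  if (model$attention_mode == "none") {
    att <- list(f = fused, masks = list(), cache = NULL)
  } else {
    att <- cram_batch_forward(fused, cram_params_view(model), model$residual)
  }
  fdrop <- att$f
  drop_mask <- NULL
  if (train && !is.null(model$dropout_p) && model$dropout_p > 0) {
    drop_mask <- matrix(
      (runif(length(fdrop)) >= model$dropout_p) / (1 - model$dropout_p),
      nrow(fdrop), ncol(fdrop))
    fdrop <- fdrop * drop_mask
  }
  logits <- sweep(fdrop %*% model$params$head.W, 2, model$params$head.b, `+`)
  list(logits = logits, probs = softmax_rows(logits), fused = fused,
       masks = att$masks, refined = att$f,
       cache = list(fa = fa, fb = fb, att = att, fdrop = fdrop,
                    drop_mask = drop_mask))
}

model_batch_backward <- function(model, fw, dlogits) {
  cache <- fw$cache
  grads <- list()
  grads[["head.W"]] <- crossprod(cache$fdrop, dlogits)
  grads[["head.b"]] <- colSums(dlogits)
  df <- dlogits %*% t(model$params$head.W)
  if (!is.null(cache$drop_mask)) df <- df * cache$drop_mask
  if (model$attention_mode == "none") {
    dfused <- df
  } else {
    bk <- cram_batch_backward(df, fw$fused, cram_params_view(model),
                              cache$att$cache, model$residual)
    dfused <- bk$dx
    grads <- c(grads, bk$dparams)
  }
  d_a <- model$backbone_a$embedding
  grads <- c(grads,
             backbone_batch_backward(dfused[, seq_len(d_a), drop = FALSE],
                                     cache$fa$cache, model$params, "a"),
             backbone_batch_backward(dfused[, -seq_len(d_a), drop = FALSE],
                                     cache$fb$cache, model$params, "b"))
  grads
}

#' Single-image forward pass with exposed intermediates
#'
#' Runs the full network in evaluation mode and returns, besides the class
#' probabilities, the fused embedding and the attention masks (for
#' visualization) -- the hooks the explanation modules build on. Images are
#' standardized with the model's stored training statistics when present.
#'
#' @param model a `hybrid_model`.
#' @param image a `labeled_image` or HxWx3 array with values on the raw
#'   \[0,1\] scale.
#' @return list with `probs` (length 2, benign/malignant), `fused`,
#'   `refined`, `a1`, `a2`, and `logits`.
#' @export
model_forward <- function(model, image) {
  px <- apply_norm(as_pixel_array(image), model$norm_stats)
  fw <- model_batch_forward(model, list(px), train = FALSE)
  list(probs = drop(fw$probs), logits = drop(fw$logits),
       fused = drop(fw$fused), refined = drop(fw$refined),
       a1 = if (length(fw$masks) >= 1) drop(fw$masks[[1]]) else NULL,
       a2 = if (length(fw$masks) >= 2) drop(fw$masks[[2]]) else NULL)
}

#' Malignancy scores for a batch of images
#'
#' @param object a `hybrid_model`.
#' @param images list of `labeled_image` objects or HxWx3 arrays (raw \[0,1\]
#'   pixel scale).
#' @param batch_size internal forward batch size.
#' @param ... unused.
#' @return numeric vector of malignant-class probabilities in \[0,1\].
#'   Thresholding at 0.5 yields labels; a score of exactly 0.5 classifies as
#'   malignant (the sensitivity-favoring tie rule).
#' @export
predict.hybrid_model <- function(object, images, batch_size = 64L, ...) {
  if (inherits(images, "labeled_image") || (is.array(images) && length(dim(images)) == 3)) {
    images <- list(images)
  }
  px <- lapply(images, function(im) apply_norm(as_pixel_array(im), object$norm_stats))
  out <- numeric(length(px))
  i <- 1L
  while (i <= length(px)) {
    j <- min(i + batch_size - 1L, length(px))
    fw <- model_batch_forward(object, px[i:j], train = FALSE)
    out[i:j] <- fw$probs[, 2]
    i <- j + 1L
  }
  out
}

#' Hard labels from malignancy scores
#' @param scores numeric vector in \[0,1\].
#' @param threshold decision threshold; scores `>= threshold` are malignant.
#' @export
classify <- function(scores, threshold = 0.5) as.integer(scores >= threshold)
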