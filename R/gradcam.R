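# Gradient-weighted class activation maps for the dual-branch model.
#
# For each branch the saliency map is ReLU(sum_c alpha_c A_c), where A_c are
# the channels of the branch's final convolutional activation map (the last
# map before global average pooling) and alpha_c is the spatial average of the
# gradient of the target-class pre-softmax logit with respect to that map.
# Because the embedding is the global average of the final map, that gradient
# is spatially uniform and equals (d logit / d embedding_c) / (Hc*Wc), which
# the attention-block backward pass provides directly. Maps are bilinearly
# upsampled to image size and max-normalized.

# gradient of the target-class logit w.r.t. the fused embedding, plus the
# refined feature and caches from a single-image forward
logit_input_gradient <- function(model, px, target_class) {
  fw <- model_batch_forward(model, list(px), train = FALSE)
  donehot <- matrix(0, 1, 2); donehot[1, target_class + 1] <- 1
  df <- donehot %*% t(model$params$head.W)
  if (model$attention_mode == "none") {
    dfused <- df
  } else {
    dfused <- cram_batch_backward(df, fw$fused, cram_params_view(model),
                                  fw$cache$att$cache, model$residual,
                                  want_param_grads = FALSE)$dx
  }
  list(fw = fw, dfused = drop(dfused))
}

#' Grad-CAM saliency map of one branch
#'
#' @param model a trained `hybrid_model`.
#' @param image a `labeled_image` or HxWx3 array (raw \[0,1\] scale).
#' @param target_class class whose logit is explained (1 = malignant).
#' @param branch `"a"` or `"b"`.
#' @return an HxW `saliency_map`: nonnegative, max-normalized so the maximum
#'   is 1; an all-zero map is returned (not an error) when the ReLU output is
#'   identically zero.
#' @export
branch_gradcam <- function(model, image, target_class = 1L, branch = c("a", "b")) {
  if (!branch[1] %in% c("a", "b")) {
    stop_config("unknown branch '", branch[1], "'; use \"a\" or \"b\"")
  }
  branch <- match.arg(branch)
  px <- apply_norm(as_pixel_array(image), model$norm_stats)
  h <- dim(px)[1]; w <- dim(px)[2]
  gr <- logit_input_gradient(model, px, target_class)
  d_a <- model$backbone_a$embedding
  slice <- if (branch == "a") seq_len(d_a) else d_a + seq_len(model$backbone_b$embedding)
  cache <- if (branch == "a") gr$fw$cache$fa$cache else gr$fw$cache$fb$cache
  hw <- cache$h4 * cache$w4
  alpha <- gr$dfused[slice] / hw
  cam_flat <- pmax(cache$z3 %*% alpha, 0)      # ReLU of weighted channel sum
  cam <- matrix(cam_flat, cache$h4, cache$w4)
  cam <- bilinear_resize(cam, h, w)
  cam <- pmax(cam, 0)
  m <- max(cam)
  if (m > 0) cam <- cam / m
  structure(cam, class = c("saliency_map", "matrix", "array"))
}

#' Additive branch shares of a class logit
#'
#' The final dense head is linear in the refined feature, so the target-class
#' logit decomposes exactly into one additive share per branch slice:
#' `s_branch = <head_weights[slice], refined[slice]>`. The contribution
#' weights are `|s|` normalized to sum to 1 (0.5/0.5 when both shares vanish).
#'
#' @param model a `hybrid_model`.
#' @param image input image.
#' @param target_class class index (1 = malignant).
#' @return list with `share_a`, `share_b` (signed logit shares) and `w_a`,
#'   `w_b` (normalized nonnegative weights).
#' @export
branch_contributions <- function(model, image, target_class = 1L) {
  px <- apply_norm(as_pixel_array(image), model$norm_stats)
  fw <- model_batch_forward(model, list(px), train = FALSE)
  f <- drop(fw$refined)
  wcol <- model$params$head.W[, target_class + 1]
  d_a <- model$backbone_a$embedding
  s_a <- sum(wcol[seq_len(d_a)] * f[seq_len(d_a)])
  s_b <- sum(wcol[-seq_len(d_a)] * f[-seq_len(d_a)])
  tot <- abs(s_a) + abs(s_b)
  if (tot == 0) {
    w_a <- 0.5; w_b <- 0.5
  } else {
    w_a <- abs(s_a) / tot; w_b <- abs(s_b) / tot
  }
  list(share_a = s_a, share_b = s_b, w_a = w_a, w_b = w_b)
}

#' Contribution-weighted combined Grad-CAM map
#'
#' Combines the two branch maps as `w_a * map_a + w_b * map_b` with the
#' additive-share weights of [branch_contributions()], then max-normalizes.
#'
#' @inheritParams branch_gradcam
#' @return an HxW `saliency_map`.
#' @export
combined_gradcam <- function(model, image, target_class = 1L) {
  map_a <- branch_gradcam(model, image, target_class, "a")
  map_b <- branch_gradcam(model, image, target_class, "b")
  wts <- branch_contributions(model, image, target_class)
  cam <- wts$w_a * unclass(map_a) + wts$w_b * unclass(map_b)
  m <- max(cam)
  if (m > 0) cam <- cam / m else {
    warning("both branch Grad-CAM maps are zero; returning an all-zero map")
  }
  structure(cam, class = c("saliency_map", "matrix", "array"),
            weights = c(a = wts$w_a, b = wts$w_b))
}
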