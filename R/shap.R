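# Superpixel-level Shapley attribution.
#
# Images are oversegmented into ~k compact superpixels (SLIC-style windowed
# k-means on rgb + position with a compactness weight). Each superpixel is a
# player in a cooperative game whose value function is the model output on
# the image with the absent superpixels painted with the image's global mean
# color. kernel_shap estimates Shapley values by the kernel-weighted
# constrained least squares of Kernel SHAP; exact_shapley enumerates all
# coalitions (K <= 12) as a verification oracle.

#' SLIC-style superpixel segmentation
#'
#' Grid-initialized k-means in (r, g, b, y, x) with the standard SLIC distance
#' `d_color^2 + (m/S)^2 d_xy^2` (S = expected superpixel spacing,
#' m = compactness in color units), followed by a connectivity cleanup that
#' merges stray fragments into their dominant neighbor. The procedure is
#' deterministic; the `seed` argument is accepted for interface uniformity.
#'
#' @param image a `labeled_image` or HxWx3 array.
#' @param k_target requested number of superpixels (>= 2); the achieved count
#'   lies within \[0.5, 2\] x `k_target`.
#' @param seed unused (the algorithm is deterministic); kept so all
#'   explanation entry points share a signature.
#' @param compactness spatial regularization weight in \[0,1\] color units.
#' @param n_iter k-means iterations.
#' @return a `superpixel_map`: list with `labels` (HxW integer matrix with
#'   values 0..K-1, every label occurring at least once) and `k`.
#' @export
segment_superpixels <- function(image, k_target = 50L, seed = 1L,
                                compactness = 0.2, n_iter = 10L) {
  px <- as_pixel_array(image)
  h <- dim(px)[1]; w <- dim(px)[2]
  if (k_target < 2) stop_config("k_target must be >= 2")
  if (h * w < k_target) stop_config("image has fewer pixels than k_target")
  s <- sqrt(h * w / k_target)
  ny <- max(1L, round(h / s)); nx <- max(1L, round(w / s))
  # center grid
  cy <- (seq_len(ny) - 0.5) * h / ny
  cx <- (seq_len(nx) - 0.5) * w / nx
  centers <- cbind(y = rep(cy, times = nx), x = rep(cx, each = ny))
  k0 <- nrow(centers)
  yy <- rep.int(seq_len(h), w); xx <- rep(seq_len(w), each = h)
  feat <- cbind(as.vector(px[, , 1]), as.vector(px[, , 2]), as.vector(px[, , 3]))
  cfeat <- feat[round(centers[, "y"]) + h * (round(centers[, "x"]) - 1), , drop = FALSE]
  m2 <- (compactness / s)^2
  lab <- integer(h * w)
  for (it in seq_len(n_iter)) {
    best <- rep(Inf, h * w)
    for (k in seq_len(k0)) {
      d <- (feat[, 1] - cfeat[k, 1])^2 + (feat[, 2] - cfeat[k, 2])^2 +
           (feat[, 3] - cfeat[k, 3])^2 +
           m2 * ((yy - centers[k, "y"])^2 + (xx - centers[k, "x"])^2)
      upd <- d < best
      lab[upd] <- k
      best[upd] <- d[upd]
    }
    centers <- cbind(y = tapply(yy, lab, mean)[as.character(seq_len(k0))],
                     x = tapply(xx, lab, mean)[as.character(seq_len(k0))])
    keep <- !is.na(centers[, 1])
    for (ch in 1:3) {
      cf <- tapply(feat[, ch], lab, mean)[as.character(seq_len(k0))]
      cfeat[keep, ch] <- cf[keep]
    }
    centers[!keep, ] <- cbind(h + 10 * s, w + 10 * s)  # park empty centers
  }
  lab <- enforce_connectivity(lab, h, w, min_size = max(4L, floor(s * s / 4)))
  k_final <- length(unique(lab))
  labels <- matrix(match(lab, sort(unique(lab))) - 1L, h, w)
  structure(list(labels = labels, k = k_final), class = "superpixel_map")
}

# relabel connected components; merge fragments below min_size into the
# neighboring component with the longest shared boundary
enforce_connectivity <- function(lab, h, w, min_size) {
  p <- seq_len(h * w)
  right <- p[(p %% h) != 0]                 # vertical neighbor (next row)
  down <- p[p <= h * (w - 1)]               # horizontal neighbor (next col)
  e1 <- cbind(right, right + 1L)
  e2 <- cbind(down, down + h)
  same1 <- lab[e1[, 1]] == lab[e1[, 2]]
  same2 <- lab[e2[, 1]] == lab[e2[, 2]]
  g <- igraph::graph_from_edgelist(rbind(e1[same1, , drop = FALSE],
                                         e2[same2, , drop = FALSE]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, h * w - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  sizes <- tabulate(comp)
  all_edges <- rbind(e1, e2)
  cross <- comp[all_edges[, 1]] != comp[all_edges[, 2]]
  ce <- all_edges[cross, , drop = FALSE]
  repeat {
    small <- which(sizes > 0 & sizes < min_size)
    if (length(small) == 0) break
    changed <- FALSE
    for (sc in small) {
      touching <- c(comp[ce[comp[ce[, 1]] == sc, 2]],
                    comp[ce[comp[ce[, 2]] == sc, 1]])
      touching <- touching[touching != sc]
      if (length(touching) == 0) next
      target <- as.integer(names(which.max(table(touching))))
      sizes[target] <- sizes[target] + sizes[sc]
      sizes[sc] <- 0L
      comp[comp == sc] <- target
      changed <- TRUE
    }
    if (!changed) break
  }
  comp
}

#' Paint absent superpixels with the mean color
#'
#' Pixels belonging to superpixels outside `coalition` are replaced by the
#' image's per-channel global mean color (the whole-image mean, so no region
#' content leaks through the baseline); present pixels are untouched.
#'
#' @param image a `labeled_image` or HxWx3 array.
#' @param seg a `superpixel_map` for this image.
#' @param coalition integer vector of present superpixel labels (0-based).
#' @return an HxWx3 array (or `labeled_image`, matching the input type).
#' @export
mask_superpixels <- function(image, seg, coalition) {
  px <- as_pixel_array(image)
  if (length(coalition) && (min(coalition) < 0 || max(coalition) >= seg$k)) {
    stop_validation("coalition indices must lie in 0..K-1")
  }
  absent <- !(seg$labels %in% coalition)
  if (any(absent)) {
    for (ch in 1:3) {
      plane <- px[, , ch]
      plane[absent] <- mean(px[, , ch])
      px[, , ch] <- plane
    }
  }
  if (inherits(image, "labeled_image")) { image$pixels <- px; image } else px
}

#' Model-output closure for attribution
#'
#' Wraps a trained model as a batched scalar-valued function of images, the
#' `model_fn` consumed by [exact_shapley()] and [kernel_shap()]. The
#' malignant-class pre-softmax logit is the default target: the linear head
#' makes logit attributions better conditioned than probabilities.
#'
#' @param model a `hybrid_model`.
#' @param target `"logit"` or `"prob"`.
#' @param target_class class index (1 = malignant).
#' @param batch_size internal batch size.
#' @return `function(images) -> numeric vector`.
#' @export
as_predictor <- function(model, target = c("logit", "prob"), target_class = 1L,
                         batch_size = 64L) {
  target <- match.arg(target)
  function(images) {
    if (!is.list(images)) images <- list(images)
    px <- lapply(images, function(im) apply_norm(as_pixel_array(im), model$norm_stats))
    out <- numeric(length(px))
    i <- 1L
    while (i <= length(px)) {
      j <- min(i + batch_size - 1L, length(px))
      fw <- model_batch_forward(model, px[i:j], train = FALSE)
      out[i:j] <- if (target == "logit") fw$logits[, target_class + 1]
                  else fw$probs[, target_class + 1]
      i <- j + 1L
    }
    out
  }
}

new_shap_values <- function(phi, base_value, value_full, method) {
  structure(list(phi = as.numeric(phi), base_value = base_value,
                 value_full = value_full, method = method),
            class = "shap_values")
}

#' @export
print.shap_values <- function(x, ...) {
  cat(sprintf("%s Shapley values over %d superpixels\n", x$method, length(x$phi)))
  cat(sprintf("  base %.5f + sum(phi) %.5f = %.5f (full-image output %.5f)\n",
              x$base_value, sum(x$phi), x$base_value + sum(x$phi), x$value_full))
  invisible(x)
}

eval_coalitions <- function(model_fn, image, seg, coalitions, batch_size = 64L) {
  out <- numeric(length(coalitions))
  i <- 1L
  while (i <= length(coalitions)) {
    j <- min(i + batch_size - 1L, length(coalitions))
    imgs <- lapply(coalitions[i:j], function(s) mask_superpixels(image, seg, s))
    out[i:j] <- model_fn(imgs)
    i <- j + 1L
  }
  out
}

#' Exact Shapley values by full coalition enumeration
#'
#' Computes `phi_i = sum_S (|S|! (K-|S|-1)! / K!) (v(S+i) - v(S))` with the
#' value function `v(S)` = model output on the image with only coalition `S`
#' present (everything else mean-masked). Requires `2^K` model evaluations, so
#' it refuses K > 12; it exists to verify the kernel estimator. The efficiency
#' identity `base + sum(phi) = v(full)` holds to machine precision.
#'
#' @param model_fn batched scalar model function (see [as_predictor()]).
#' @param image the image being explained.
#' @param seg its `superpixel_map` (K <= 12).
#' @return a `shap_values` object (`phi`, `base_value`, `value_full`).
#' @export
exact_shapley <- function(model_fn, image, seg) {
  k <- seg$k
  if (k > 12) {
    stop_config("exact enumeration needs 2^K model calls; K = ", k,
                " > 12 -- use kernel_shap() instead")
  }
  n_sets <- bitwShiftL(1L, k)
  masks <- 0:(n_sets - 1)
  coalitions <- lapply(masks, function(m) which(bitwAnd(m, bitwShiftL(1L, 0:(k - 1))) > 0) - 1L)
  v <- eval_coalitions(model_fn, image, seg, coalitions)
  popcount <- vapply(coalitions, length, integer(1))
  wtab <- factorial(0:(k - 1)) * factorial(k - (0:(k - 1)) - 1) / factorial(k)
  phi <- numeric(k)
  for (i in seq_len(k)) {
    bit <- bitwShiftL(1L, i - 1L)
    without <- masks[bitwAnd(masks, bit) == 0]
    sz <- popcount[without + 1L]
    phi[i] <- sum(wtab[sz + 1L] * (v[without + bit + 1L] - v[without + 1L]))
  }
  new_shap_values(phi, base_value = v[1], value_full = v[n_sets], "exact")
}

shapley_kernel_weight <- function(k, s) {
  (k - 1) / (choose(k, s) * s * (k - s))
}

#' Kernel SHAP estimate of superpixel Shapley values
#'
#' Weighted least squares over binary coalition vectors with the Shapley
#' kernel weights, solved under the efficiency constraint
#' `sum(phi) = v(full) - v(empty)` (so efficiency holds exactly by
#' construction). When `n_samples` covers all `2^K - 2` proper coalitions the
#' full enumeration is used and the estimate equals the exact Shapley values;
#' otherwise coalition sizes are drawn from the kernel distribution and
#' subsets uniformly within size, deterministically per seed.
#'
#' @inheritParams exact_shapley
#' @param n_samples number of coalition evaluations (>= K + 2).
#' @param seed integer seed for coalition sampling.
#' @return a `shap_values` object.
#' @export
kernel_shap <- function(model_fn, image, seg, n_samples = 2048L, seed = 1L) {
  k <- seg$k
  if (k < 2) stop_config("need at least 2 superpixels")
  if (n_samples < k + 2) stop_config("n_samples must be at least K + 2 = ", k + 2)
  v_empty <- eval_coalitions(model_fn, image, seg, list(integer(0)))
  v_full <- eval_coalitions(model_fn, image, seg, list(0:(k - 1)))
  total <- v_full - v_empty

  full_enum <- k <= 24 && (2^k - 2) <= n_samples
  if (full_enum) {
    masks <- setdiff(0:(2^k - 1), c(0, 2^k - 1))
    z <- t(vapply(masks, function(m) as.integer(bitwAnd(m, bitwShiftL(1L, 0:(k - 1))) > 0),
                  integer(k)))
  } else {
    z <- with_seed(seed, {
      sizes_p <- (k - 1) / ((1:(k - 1)) * (k - (1:(k - 1))))
      sz <- sample(1:(k - 1), n_samples, replace = TRUE, prob = sizes_p)
      t(vapply(sz, function(s) {
        row <- integer(k); row[sample.int(k, s)] <- 1L; row
      }, integer(k)))
    })
    z <- unique(z)
  }
  sizes <- rowSums(z)
  wts <- shapley_kernel_weight(k, sizes)
  coalitions <- lapply(seq_len(nrow(z)), function(r) which(z[r, ] == 1L) - 1L)
  y <- eval_coalitions(model_fn, image, seg, coalitions)

  # eliminate phi_K via the efficiency constraint, then weighted least squares
  zk <- z[, k]
  xmat <- z[, -k, drop = FALSE] - zk
  yadj <- y - v_empty - zk * total
  xtw <- t(xmat * wts)
  phi_rest <- tryCatch(solve(xtw %*% xmat, xtw %*% yadj),
                       error = function(e) {
                         stop_config("singular regression system; increase n_samples")
                       })
  phi <- c(phi_rest, total - sum(phi_rest))
  new_shap_values(phi, base_value = v_empty, value_full = v_full,
                  if (full_enum) "kernel (full enumeration)" else "kernel")
}

#' Diverging red/blue rendering of superpixel attributions
#'
#' Colors every superpixel on a symmetric scale `+-max(|phi|)`: red pushes
#' toward the malignant class, blue toward benign, white is neutral; deeper
#' color means higher magnitude. With `alpha > 0` the rendering is blended
#' over the original image.
#'
#' @param image the explained image.
#' @param seg its `superpixel_map`.
#' @param phi length-K attribution vector (or a `shap_values` object).
#' @param alpha blending weight of the original image in \[0,1).
#' @return an HxWx3 array in \[0,1\].
#' @export
shap_overlay <- function(image, seg, phi, alpha = 0) {
  if (inherits(phi, "shap_values")) phi <- phi$phi
  if (length(phi) != seg$k) stop_validation("phi length must equal K")
  px <- as_pixel_array(image)
  h <- dim(px)[1]; w <- dim(px)[2]
  scale <- max(abs(phi))
  sat <- if (scale > 0) phi / scale else rep(0, length(phi))
  smap <- matrix(sat[seg$labels + 1L], h, w)
  out <- array(1, dim = c(h, w, 3))
  pos <- pmax(smap, 0); neg <- pmax(-smap, 0)
  out[, , 1] <- 1 - neg           # red channel reduced by benign evidence
  out[, , 2] <- 1 - pos - neg     # green reduced by any evidence
  out[, , 3] <- 1 - pos           # blue channel reduced by malignant evidence
  out <- clamp01(out)
  if (alpha > 0) out <- clamp01(alpha * px + (1 - alpha) * out)
  out
}
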