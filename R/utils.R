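#' @importFrom stats rnorm runif sd plogis pchisq pbinom
#' @importFrom utils write.csv read.csv head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(structure(class = c("cramnet_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_validation <- function(...) {
  stop(structure(class = c("cramnet_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_finite <- function(x, what) {
  if (!all(is.finite(x))) stop_validation(what, " contains non-finite values")
  invisible(x)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Derive a module-specific seed from a master seed
#'
#' A single run seed fans out to per-component seeds so that, e.g., dataset
#' generation and weight initialization draw from independent, individually
#' reproducible streams. The derivation is a fixed affine map modulo a Mersenne
#' prime, keeping results inside the 32-bit integer range.
#'
#' @param seed master integer seed.
#' @param k small non-negative integer identifying the component stream.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, k = 0L) {
  s <- (as.double(seed) %% 1e6) * 131 + as.double(k) * 7919 + 17
  as.integer(s %% 2147483647)
}

with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

#' Bilinear resize of a 2-d map
#'
#' Upsamples (or downsamples) a numeric matrix to a target spatial size using
#' bilinear interpolation with pixel-center alignment; the standard smoothing
#' step when projecting coarse class-activation maps back onto the input image.
#'
#' @param m numeric matrix.
#' @param out_h,out_w target dimensions.
#' @return numeric matrix of size `out_h` x `out_w`.
#' @export
bilinear_resize <- function(m, out_h, out_w) {
  h <- nrow(m); w <- ncol(m)
  if (h == out_h && w == out_w) return(m)
  # pixel-center alignment: output center u maps to input coordinate
  ys <- ((seq_len(out_h) - 0.5) * h / out_h) + 0.5 - 1  # in [0.5-1, ...] 0-based centers
  xs <- ((seq_len(out_w) - 0.5) * w / out_w) + 0.5 - 1
  y0 <- pmin(pmax(floor(ys), 0), h - 1); y1 <- pmin(y0 + 1, h - 1)
  x0 <- pmin(pmax(floor(xs), 0), w - 1); x1 <- pmin(x0 + 1, w - 1)
  wy <- pmin(pmax(ys - y0, 0), 1); wx <- pmin(pmax(xs - x0, 0), 1)
  m00 <- m[y0 + 1, x0 + 1, drop = FALSE]; m01 <- m[y0 + 1, x1 + 1, drop = FALSE]
  m10 <- m[y1 + 1, x0 + 1, drop = FALSE]; m11 <- m[y1 + 1, x1 + 1, drop = FALSE]
  top <- m00 * outer(rep(1, out_h), 1 - wx) + m01 * outer(rep(1, out_h), wx)
  bot <- m10 * outer(rep(1, out_h), 1 - wx) + m11 * outer(rep(1, out_h), wx)
  top * outer(1 - wy, rep(1, out_w)) + bot * outer(wy, rep(1, out_w))
}

# binary morphology on logical matrices with a square structuring element
dilate_mask <- function(m, r = 1L) {
  out <- m
  h <- nrow(m); w <- ncol(m)
  for (dy in -r:r) for (dx in -r:r) {
    if (dy == 0 && dx == 0) next
    ys <- pmin(pmax(seq_len(h) + dy, 1), h)
    xs <- pmin(pmax(seq_len(w) + dx, 1), w)
    out <- out | m[ys, xs, drop = FALSE]
  }
  out
}

erode_mask <- function(m, r = 1L) !dilate_mask(!m, r)

close_mask <- function(m, r = 1L) erode_mask(dilate_mask(m, r), r)
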