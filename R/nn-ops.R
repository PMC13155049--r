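# Minimal CPU neural-network primitives.
#
# Activations for a batch of N images at spatial size HxW with C channels are
# stored as a (H*W*N) x C matrix whose row index enumerates (h, w, n) in
# column-major order. A 3x3 same-padded convolution is then nine gathers (one
# per kernel offset) followed by matrix products, which keeps everything in
# BLAS. Gather index vectors are cached per (H, W, N, dy, dx); out-of-image
# positions point at a sentinel zero row, which also makes the transposed
# (backward) gathers handle zero padding for free.

.nn_cache <- new.env(parent = emptyenv())

shift_index <- function(h, w, n, dy, dx) {
  key <- paste(h, w, n, dy, dx, sep = ",")
  idx <- .nn_cache[[key]]
  if (!is.null(idx)) return(idx)
  hh <- rep.int(seq_len(h), w)
  ww <- rep(seq_len(w), each = h)
  sh <- hh + dy; sw <- ww + dx
  valid <- sh >= 1 & sh <= h & sw >= 1 & sw <= w
  src <- sh + h * (sw - 1)
  sentinel <- h * w * n + 1L
  one <- ifelse(valid, src, NA_integer_)
  idx <- integer(h * w * n)
  for (i in seq_len(n)) {
    off <- h * w * (i - 1L)
    block <- one + off
    block[!valid] <- sentinel
    idx[(off + 1L):(off + h * w)] <- block
  }
  .nn_cache[[key]] <- idx
  idx
}

gather_shift <- function(x, h, w, n, dy, dx) {
  idx <- shift_index(h, w, n, dy, dx)
  rbind(x, 0)[idx, , drop = FALSE]
}

conv3x3_forward <- function(x, kern, bias, h, w, n) {
  cout <- dim(kern)[4]
  y <- matrix(rep(bias, each = h * w * n), h * w * n, cout)
  for (ky in 1:3) for (kx in 1:3) {
    y <- y + gather_shift(x, h, w, n, ky - 2L, kx - 2L) %*% kern[ky, kx, , ]
  }
  y
}

conv3x3_backward <- function(dy, x, kern, h, w, n) {
  cin <- dim(kern)[3]; cout <- dim(kern)[4]
  dkern <- array(0, dim = dim(kern))
  dx <- matrix(0, h * w * n, cin)
  for (ky in 1:3) for (kx in 1:3) {
    xs <- gather_shift(x, h, w, n, ky - 2L, kx - 2L)
    dkern[ky, kx, , ] <- crossprod(xs, dy)
    dx <- dx + gather_shift(dy, h, w, n, 2L - ky, 2L - kx) %*% t(kern[ky, kx, , ])
  }
  list(dx = dx, dkern = dkern, dbias = colSums(dy))
}

pool_index <- function(h, w, n) {
  key <- paste("pool", h, w, n, sep = ",")
  idx <- .nn_cache[[key]]
  if (!is.null(idx)) return(idx)
  h2 <- h %/% 2L; w2 <- w %/% 2L
  hh <- rep.int(seq_len(h2), w2)
  ww <- rep(seq_len(w2), each = h2)
  idx <- vector("list", 4)
  k <- 0L
  for (b in 0:1) for (a in 0:1) {
    k <- k + 1L
    src1 <- (2L * hh - 1L + a) + h * (2L * ww - 2L + b)
    idx[[k]] <- as.vector(outer(src1, h * w * (seq_len(n) - 1L), `+`))
  }
  .nn_cache[[key]] <- idx
  idx
}

avgpool2_forward <- function(x, h, w, n) {
  idx <- pool_index(h, w, n)
  (x[idx[[1]], , drop = FALSE] + x[idx[[2]], , drop = FALSE] +
   x[idx[[3]], , drop = FALSE] + x[idx[[4]], , drop = FALSE]) / 4
}

avgpool2_backward <- function(dy, h, w, n, cin) {
  idx <- pool_index(h, w, n)
  dx <- matrix(0, h * w * n, cin)
  g <- dy / 4
  for (k in 1:4) dx[idx[[k]], ] <- g
  dx
}

gap_forward <- function(x, h, w, n) {
  grp <- rep(seq_len(n), each = h * w)
  rowsum(x, grp, reorder = FALSE) / (h * w)
}

gap_backward <- function(dy, h, w, n) {
  dy[rep(seq_len(n), each = h * w), , drop = FALSE] / (h * w)
}

relu <- function(x) { x[x < 0] <- 0; x }

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# mean cross-entropy and logits gradient for one-hot integer labels (0/1)
softmax_ce <- function(logits, labels) {
  p <- softmax_rows(logits)
  n <- nrow(p)
  picked <- p[cbind(seq_len(n), labels + 1L)]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dlogits <- p
  dlogits[cbind(seq_len(n), labels + 1L)] <-
    dlogits[cbind(seq_len(n), labels + 1L)] - 1
  list(loss = loss, dlogits = dlogits / n, probs = p)
}

he_normal <- function(dims, fan_in) {
  array(rnorm(prod(dims), 0, sqrt(2 / fan_in)), dim = dims)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, trainable,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    if (!trainable[[nm]]) next
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# stack a list of HxWx3 arrays into the (H*W*N) x 3 activation layout
batch_to_matrix <- function(images) {
  do.call(rbind, lapply(images, function(a) matrix(a, prod(dim(a)[1:2]), 3)))
}
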