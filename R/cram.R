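# Recurrent gated channel attention over a fused feature vector.
#
# The fused embedding X (concatenation of the two branch embeddings) is
# refined by two sequential sigmoid-gated attention steps with ReLU
# nonlinearities and an identity residual:
#
#   A1 = sigmoid(f1(X));   Y' = ReLU(X * A1)
#   A2 = sigmoid(f2(Y'));  Z' = ReLU(Y' * A2)
#   F  = X + Z'
#
# where each gating transform f_k is a small two-layer dense network
# (input -> hidden, ReLU -> output of feature length) with its own weights.
# With all gate weights zero every mask is exactly 0.5 ("neutral" attention),
# and the residual guarantees F_i = X_i wherever X_i <= 0.

#' Initialize attention parameters
#'
#' Weights are drawn He-normal (sd = sqrt(2/fan_in)); all biases start at 0 so
#' the gating sigmoids open at exactly 0.5, a neutral initial attention.
#'
#' @param feature_length length of the fused feature vector (2D).
#' @param hidden_width width of the hidden layer inside each gating transform.
#'   The full-width variant (`hidden_width = feature_length`) is available, but
#'   the default in [build_model()] is narrower to keep the parameter budget of
#'   the attention block and classifier head in the low millions at
#'   `feature_length = 2560`.
#' @param seed integer seed.
#' @param steps number of sequential gated attention steps (2 by default; 1
#'   gives the single-pass squeeze-and-excitation-style ablation).
#' @return a `cram_params` object.
#' @export
init_cram <- function(feature_length, hidden_width, seed = 1L, steps = 2L) {
  if (feature_length < 1 || hidden_width < 1 || steps < 1) {
    stop_config("feature_length, hidden_width and steps must be positive")
  }
  with_seed(seed, {
    step_list <- lapply(seq_len(steps), function(k) {
      list(W1 = he_normal(c(feature_length, hidden_width), feature_length),
           b1 = numeric(hidden_width),
           W2 = he_normal(c(hidden_width, feature_length), hidden_width),
           b2 = numeric(feature_length))
    })
    structure(list(steps = step_list,
                   feature_length = as.integer(feature_length),
                   hidden_width = as.integer(hidden_width)),
              class = "cram_params")
  })
}

#' Number of parameters in an attention block
#' @param params a `cram_params` object.
#' @export
cram_n_params <- function(params) {
  sum(vapply(params$steps, function(s) {
    length(s$W1) + length(s$b1) + length(s$W2) + length(s$b2)
  }, numeric(1)))
}

#' Gating transform: pre-sigmoid logits of one attention step
#'
#' Computes `W2' ReLU(W1' x + b1) + b2`, the logits whose sigmoid forms the
#' channel-attention mask.
#'
#' @param x numeric vector (or matrix with samples in rows).
#' @param step_params one element of `cram_params$steps`.
#' @return vector (or matrix) of gate logits, same feature length as `x`.
#' @export
gating_transform <- function(x, step_params) {
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, 1) else x
  if (ncol(xm) != nrow(step_params$W1)) {
    stop_validation("input length ", ncol(xm), " does not match gating weights (",
                    nrow(step_params$W1), ")")
  }
  hidden <- relu(sweep(xm %*% step_params$W1, 2, step_params$b1, `+`))
  out <- sweep(hidden %*% step_params$W2, 2, step_params$b2, `+`)
  if (vec) drop(out) else out
}

cram_batch_forward <- function(x, params, residual = TRUE) {
  cur <- x
  masks <- list(); cache <- list()
  for (k in seq_along(params$steps)) {
    sp <- params$steps[[k]]
    hidden <- relu(sweep(cur %*% sp$W1, 2, sp$b1, `+`))
    logits <- sweep(hidden %*% sp$W2, 2, sp$b2, `+`)
    a <- sigmoid(logits)
    y <- cur * a
    yp <- relu(y)
    cache[[k]] <- list(input = cur, hidden = hidden, a = a, y = y)
    masks[[k]] <- a
    cur <- yp
  }
  f <- if (residual) x + cur else cur
  list(f = f, masks = masks, cache = cache)
}

# backward pass; returns gradient w.r.t. the fused input and (optionally)
# w.r.t. all step parameters, named cram.s<k>.{W1,b1,W2,b2}
cram_batch_backward <- function(df, x, params, cache, residual = TRUE,
                                want_param_grads = TRUE) {
  dcur <- df
  dx_extra <- if (residual) df else 0
  dparams <- list()
  for (k in rev(seq_along(params$steps))) {
    sp <- params$steps[[k]]
    ck <- cache[[k]]
    dy <- dcur * (ck$y > 0)            # through ReLU(Y)
    dinput <- dy * ck$a                # through X * A (input path)
    da <- dy * ck$input                # through X * A (mask path)
    dlogits <- da * ck$a * (1 - ck$a)  # through sigmoid
    if (want_param_grads) {
      dparams[[paste0("cram.s", k, ".W2")]] <- crossprod(ck$hidden, dlogits)
      dparams[[paste0("cram.s", k, ".b2")]] <- colSums(dlogits)
    }
    dhidden <- (dlogits %*% t(sp$W2)) * (ck$hidden > 0)
    if (want_param_grads) {
      dparams[[paste0("cram.s", k, ".W1")]] <- crossprod(ck$input, dhidden)
      dparams[[paste0("cram.s", k, ".b1")]] <- colSums(dhidden)
    }
    dinput <- dinput + dhidden %*% t(sp$W1)
    dcur <- dinput
  }
  list(dx = dcur + dx_extra, dparams = dparams)
}

#' Forward pass of the recurrent gated attention block
#'
#' Applies the two sequential sigmoid-gated attention steps with ReLU
#' nonlinearities and the identity residual to a fused feature vector, and
#' returns the refined feature together with both attention masks (useful for
#' visualizing which channels the block amplifies).
#'
#' @param x fused feature vector (length `params$feature_length`), or a matrix
#'   with one sample per row.
#' @param params a `cram_params` object from [init_cram()].
#' @param residual keep the identity residual connection (disable only for
#'   ablation; training without it is markedly less stable).
#' @return list with `f` (refined feature), `a1`, `a2` (attention masks, each
#'   entry strictly inside (0,1); `a2` is `NULL` for a single-step block) and
#'   `masks` (list of all step masks).
#' @export
cram_forward <- function(x, params, residual = TRUE) {
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, 1) else x
  check_finite(xm, "fused feature")
  if (ncol(xm) != params$feature_length) {
    stop_validation("feature length ", ncol(xm), " does not match params (",
                    params$feature_length, ")")
  }
  fw <- cram_batch_forward(xm, params, residual)
  pick <- function(m) if (is.null(m)) NULL else if (vec) drop(m) else m
  list(f = pick(fw$f),
       a1 = pick(fw$masks[[1]]),
       a2 = if (length(fw$masks) >= 2) pick(fw$masks[[2]]) else NULL,
       masks = lapply(fw$masks, pick))
}
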