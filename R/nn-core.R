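# Low-level neural-network primitives shared by the autoencoder, the
# prediction networks and the learned optimizer. Activation arrays are
# column-major with dim (H, W, C, B); dense activations are (B x features)
# matrices; dense weights are stored input x output.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

relu_bwd <- function(gy, y) {
  gy[y <= 0] <- 0
  gy
}

# Leaky ReLU (used inside the autoencoder, where fully rectifying signed
# sEMG invites dead units; slope fixed at 0.1). Branch-free forms:
# max(x, 0.1 x) = 0.55 x + 0.45 |x|; slope = 0.55 + 0.45 sign(y).
lrelu <- function(x) 0.55 * x + 0.45 * abs(x)

lrelu_bwd <- function(gy, y) gy * (0.55 + 0.45 * sign(y))

sigmoid <- function(x) 1 / (1 + exp(-x))

# Kaiming-uniform fan-in initialization (gain for ReLU); biases start at zero.
init_conv_layer <- function(kh, kw, cin, cout) {
  fan_in <- kh * kw * cin
  bound <- sqrt(6 / fan_in)
  list(w = array(stats::runif(kh * kw * cin * cout, -bound, bound),
                 dim = c(kh, kw, cin, cout)),
       b = numeric(cout))
}

init_dense_layer <- function(n_in, n_out) {
  bound <- sqrt(6 / n_in)
  list(w = matrix(stats::runif(n_in * n_out, -bound, bound), n_in, n_out),
       b = numeric(n_out))
}

add_channel_bias <- function(y, b) {
  d <- dim(y)
  y + rep(rep(b, each = d[1L] * d[2L]), times = d[4L])
}

channel_bias_grad <- function(gy) {
  d <- dim(gy)
  cs <- colSums(matrix(gy, nrow = d[1L] * d[2L]))
  if (d[4L] == 1L) cs else rowSums(matrix(cs, d[3L], d[4L]))
}

# Valid convolution, stride 1.
conv_fwd <- function(x, layer) .conv_fwd_cpp(x, layer$w, layer$b)

conv_bwd <- function(x, layer, gy, need_dx = TRUE) {
  list(dx = if (need_dx) .conv_bwd_input_cpp(gy, layer$w, dim(x)[1L], dim(x)[2L]),
       dw = .conv_bwd_filter_cpp(x, gy),
       db = channel_bias_grad(gy))
}

# Transposed convolution (adjoint of valid conv). Filters have dim
# (kh, kw, c_out, c_in): the layer maps c_in maps to larger c_out maps.
tconv_fwd <- function(x, layer) {
  kh <- dim(layer$w)[1L]; kw <- dim(layer$w)[2L]
  y <- .conv_bwd_input_cpp(x, layer$w, dim(x)[1L] + kh - 1L, dim(x)[2L] + kw - 1L)
  add_channel_bias(y, layer$b)
}

tconv_bwd <- function(x, layer, gy, need_dx = TRUE) {
  list(dx = if (need_dx) .conv_fwd_cpp(gy, layer$w, NULL),
       dw = .conv_bwd_filter_cpp(gy, x),
       db = channel_bias_grad(gy))
}

dense_fwd <- function(x, layer) {
  sweep(x %*% layer$w, 2L, layer$b, "+")
}

dense_bwd <- function(x, layer, gy, need_dx = TRUE) {
  list(dx = if (need_dx) gy %*% t(layer$w),
       dw = crossprod(x, gy),
       db = colSums(gy))
}

# In-place-style SGD step over a nested parameter list mirrored by `grads`.
sgd_update <- function(params, grads, lr) {
  if (is.list(params)) {
    for (i in seq_along(params)) {
      params[[i]] <- sgd_update(params[[i]], grads[[i]], lr)
    }
    params
  } else {
    params - lr * grads
  }
}

# Classical-momentum SGD: v <- mu v + g; theta <- theta - lr v.
# Returns list(params, velocity).
sgd_momentum_update <- function(params, grads, velocity, lr, momentum) {
  if (is.list(params)) {
    for (i in seq_along(params)) {
      r <- sgd_momentum_update(params[[i]], grads[[i]], velocity[[i]], lr,
                               momentum)
      params[[i]] <- r$params
      velocity[[i]] <- r$velocity
    }
    list(params = params, velocity = velocity)
  } else {
    v <- momentum * velocity + grads
    list(params = params - lr * v, velocity = v)
  }
}

zero_like <- function(params) {
  if (is.list(params)) lapply(params, zero_like) else params * 0
}

accumulate_grads <- function(a, b, weight = 1) {
  if (is.list(a)) {
    for (i in seq_along(a)) a[[i]] <- accumulate_grads(a[[i]], b[[i]], weight)
    a
  } else {
    a + weight * b
  }
}

# Adam update over nested parameter lists. `state` holds first/second
# moments and the step counter; pass the returned state back in.
adam_init <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_update <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1L
  step <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (i in seq_along(p)) {
        r <- step(p[[i]], g[[i]], m[[i]], v[[i]])
        out_p[[i]] <- r$p; out_m[[i]] <- r$m; out_v[[i]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mhat <- m / (1 - beta1^state$t)
      vhat <- v / (1 - beta2^state$t)
      list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
    }
  }
  r <- step(params, grads, state$m, state$v)
  state$m <- r$m; state$v <- r$v
  list(params = r$p, state = state)
}

# One optimizer step dispatching on method; `opt_state` carries velocity or
# Adam moments.
apply_update <- function(method, params, grads, opt_state, lr, momentum) {
  if (method == "adam") {
    r <- adam_update(params, grads, opt_state, lr)
    list(params = r$params, state = r$state)
  } else {
    r <- sgd_momentum_update(params, grads, opt_state, lr, momentum)
    list(params = r$params, state = r$velocity)
  }
}

init_opt_state <- function(method, params) {
  if (method == "adam") adam_init(params) else zero_like(params)
}

# Step-decay learning-rate schedule: lr * factor^floor(epoch / period),
# epochs counted from zero.
lr_schedule <- function(lr0, factor, period, epoch) {
  lr0 * factor^(epoch %/% period)
}

#' Save or load a network checkpoint
#'
#' Serializes a trained network (`cae`, `intent_predictor` or
#' `learned_optimizer`) together with its architecture metadata to one file;
#' `read_checkpoint` restores the exact object, so training can be split
#' across sessions and adapted models can be archived.
#'
#' @param model a `cae`, `intent_predictor` or `learned_optimizer`.
#' @param path checkpoint file path.
#' @return `read_checkpoint` returns the restored model.
#' @export
write_checkpoint <- function(model, path) {
  stopifnot(inherits(model, c("cae", "intent_predictor", "learned_optimizer")))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, c("cae", "intent_predictor", "learned_optimizer"))) {
    stop("not a recognized network checkpoint")
  }
  model
}
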