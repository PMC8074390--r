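# Batched multi-layer LSTM with full backpropagation through time, used both
# by the motion-prediction networks (3 x 200 units) and by the coordinatewise
# learned optimizer (3 x 40 units, one time step per adaptation iteration with
# persistent state). Gate blocks are ordered input, forget, cell, output.

lstm_init <- function(n_in, n_hidden, n_layers) {
  bound <- 1 / sqrt(n_hidden)
  lapply(seq_len(n_layers), function(l) {
    ni <- if (l == 1L) n_in else n_hidden
    list(wx = matrix(stats::runif(ni * 4L * n_hidden, -bound, bound), ni, 4L * n_hidden),
         wh = matrix(stats::runif(n_hidden * 4L * n_hidden, -bound, bound), n_hidden, 4L * n_hidden),
         b = stats::runif(4L * n_hidden, -bound, bound))
  })
}

lstm_zero_state <- function(params, batch) {
  H <- ncol(params[[1L]]$wh) / 4L
  list(h = lapply(params, function(.) matrix(0, batch, H)),
       c = lapply(params, function(.) matrix(0, batch, H)))
}

# x: (B, T, n_in) array. state: optional initial state (as returned).
# Returns h: (B, T, H) top-layer outputs, final state, and a backprop cache.
lstm_fwd <- function(params, x, state = NULL) {
  B <- dim(x)[1L]; TT <- dim(x)[2L]
  L <- length(params)
  H <- ncol(params[[1L]]$wh) / 4L
  if (is.null(state)) state <- lstm_zero_state(params, B)
  hs <- array(0, dim = c(B, TT, H))
  cache <- vector("list", L)
  for (l in seq_len(L)) cache[[l]] <- vector("list", TT)
  h <- state$h; c <- state$c
  idx_i <- seq_len(H); idx_f <- H + idx_i; idx_g <- 2L * H + idx_i; idx_o <- 3L * H + idx_i
  for (t in seq_len(TT)) {
    inp <- matrix(x[, t, ], B, dim(x)[3L])
    for (l in seq_len(L)) {
      p <- params[[l]]
      z <- sweep(inp %*% p$wx + h[[l]] %*% p$wh, 2L, p$b, "+")
      gi <- sigmoid(z[, idx_i, drop = FALSE])
      gf <- sigmoid(z[, idx_f, drop = FALSE])
      gg <- tanh(z[, idx_g, drop = FALSE])
      go <- sigmoid(z[, idx_o, drop = FALSE])
      cp <- c[[l]]
      cn <- gf * cp + gi * gg
      tc <- tanh(cn)
      hn <- go * tc
      cache[[l]][[t]] <- list(inp = inp, hp = h[[l]], cp = cp,
                              gi = gi, gf = gf, gg = gg, go = go, tc = tc)
      h[[l]] <- hn
      c[[l]] <- cn
      inp <- hn
    }
    hs[, t, ] <- h[[L]]
  }
  list(h = hs, state = list(h = h, c = c), cache = cache)
}

# gh_out: (B, T, H) gradient w.r.t. the top-layer outputs (NULL for none);
# gstate: gradient w.r.t. the final state (for chaining across calls).
# Returns parameter grads, gx (B, T, n_in) and the gradient w.r.t. the
# initial state.
lstm_bwd <- function(params, cache, gh_out = NULL, gstate = NULL) {
  L <- length(params)
  TT <- length(cache[[1L]])
  B <- nrow(cache[[1L]][[1L]]$inp)
  H <- ncol(params[[1L]]$wh) / 4L
  grads <- lapply(params, function(p) list(wx = p$wx * 0, wh = p$wh * 0, b = p$b * 0))
  # grad flowing into each layer's output at each time step (from layer above)
  gtop <- vector("list", L)
  for (l in seq_len(L)) gtop[[l]] <- array(0, dim = c(B, TT, H))
  if (!is.null(gh_out)) gtop[[L]] <- gtop[[L]] + gh_out
  gx <- NULL
  gh0 <- vector("list", L); gc0 <- vector("list", L)
  for (l in rev(seq_len(L))) {
    p <- params[[l]]
    carry_h <- if (!is.null(gstate)) gstate$h[[l]] else matrix(0, B, H)
    carry_c <- if (!is.null(gstate)) gstate$c[[l]] else matrix(0, B, H)
    ni <- nrow(p$wx)
    gx_l <- array(0, dim = c(B, TT, ni))
    for (t in rev(seq_len(TT))) {
      cc <- cache[[l]][[t]]
      gh <- matrix(gtop[[l]][, t, ], B, H) + carry_h
      gc <- carry_c + gh * cc$go * (1 - cc$tc^2)
      gi_pre <- gc * cc$gg * cc$gi * (1 - cc$gi)
      gf_pre <- gc * cc$cp * cc$gf * (1 - cc$gf)
      gg_pre <- gc * cc$gi * (1 - cc$gg^2)
      go_pre <- gh * cc$tc * cc$go * (1 - cc$go)
      gz <- cbind(gi_pre, gf_pre, gg_pre, go_pre)
      grads[[l]]$wx <- grads[[l]]$wx + crossprod(cc$inp, gz)
      grads[[l]]$wh <- grads[[l]]$wh + crossprod(cc$hp, gz)
      grads[[l]]$b <- grads[[l]]$b + colSums(gz)
      gx_l[, t, ] <- gz %*% t(p$wx)
      carry_h <- gz %*% t(p$wh)
      carry_c <- gc * cc$gf
    }
    gh0[[l]] <- carry_h
    gc0[[l]] <- carry_c
    if (l > 1L) gtop[[l - 1L]] <- gtop[[l - 1L]] + gx_l else gx <- gx_l
  }
  list(grads = grads, gx = gx, gstate0 = list(h = gh0, c = gc0))
}
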