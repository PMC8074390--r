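# Convolutional autoencoder for sEMG feature compression.
#
# Encoder ("Single-Kernel" temporal stack then "Multi-Kernels" 2-D stack):
#   9x200 input -> conv 1x105 (20 maps)  -> 9x96
#              -> conv 1x55  (40 maps)  -> 9x42
#              -> conv 1x30  (80 maps)  -> 9x13
#   synergy rearrangement of the channel axis in 5 groups of 16 maps
#              -> conv 4x4   (40 maps)  -> 6x10
#              -> conv 4x4   (40 maps)  -> 3x7   (the compressed feature)
# Decoder mirrors the kernel chain with transposed convolutions (independent
# parameter values) back to 9x200; the inverse channel permutation is applied
# at the mirrored position so the reconstruction is in original channel
# order. A leaky ReLU (slope 0.1) follows every layer except the encoder output
# and the decoder output, which stay linear because raw sEMG is signed;
# full rectification kills the signed decoder paths (dead units).

cae_arch <- function() {
  list(enc = list(c(1L, 105L, 1L, 20L), c(1L, 55L, 20L, 40L),
                  c(1L, 30L, 40L, 80L), c(4L, 4L, 80L, 40L),
                  c(4L, 4L, 40L, 40L)),
       dec = list(c(4L, 4L, 40L, 40L), c(4L, 4L, 80L, 40L),
                  c(1L, 30L, 40L, 80L), c(1L, 55L, 20L, 40L),
                  c(1L, 105L, 1L, 20L)))
}

init_tconv_layer <- function(kh, kw, cout, cin) {
  fan_in <- kh * kw * cin
  bound <- sqrt(6 / fan_in)
  list(w = array(stats::runif(kh * kw * cout * cin, -bound, bound),
                 dim = c(kh, kw, cout, cin)),
       b = numeric(cout))
}

#' Initialize a convolutional autoencoder
#'
#' Builds the five-layer encoder / five-layer decoder sEMG autoencoder with
#' Kaiming-uniform seeded initialization. `orders` fixes the synergy-derived
#' channel permutations applied between the temporal ("Single-Kernel") and
#' 2-D ("Multi-Kernels") encoder stages; they are part of the architecture
#' and are never trained.
#'
#' @param orders a `channel_orders` object (5 permutations of the 9
#'   channels), e.g. from [derive_channel_orders()]; `NULL` gives identity
#'   permutations.
#' @param seed seed for the initialization.
#' @return An object of class `cae`.
#' @export
cae_init <- function(orders = NULL, seed = NULL) {
  if (is.null(orders)) {
    orders <- structure(rep(list(1:9), 5L), class = "channel_orders")
  }
  arch <- cae_arch()
  params <- with_seed(seed, {
    list(enc = lapply(arch$enc, function(d) {
           init_conv_layer(d[1L], d[2L], d[3L], d[4L])
         }),
         dec = lapply(arch$dec, function(d) {
           init_tconv_layer(d[1L], d[2L], d[3L], d[4L])
         }))
  })
  structure(list(params = params, orders = orders,
                 inv_orders = inverse_orders(orders),
                 trained = FALSE, history = NULL),
            class = "cae")
}

as_image_batch <- function(images) {
  d <- dim(images)
  if (length(d) == 2L) d <- c(d, 1L)
  array(images, dim = c(d[1L], d[2L], 1L, d[3L]))
}

# Full forward pass. Returns the 40 x 3 x 7 feature stack (as a
# (3, 7, 40, B) array), the 9x200 reconstruction, and activations for
# backprop when keep_cache.
cae_forward <- function(cae, images, keep_cache = FALSE) {
  p <- cae$params
  x <- as_image_batch(images)
  a1 <- lrelu(conv_fwd(x, p$enc[[1L]]))
  a2 <- lrelu(conv_fwd(a1, p$enc[[2L]]))
  a3 <- lrelu(conv_fwd(a2, p$enc[[3L]]))
  a3r <- rearrange(a3, cae$orders)
  a4 <- lrelu(conv_fwd(a3r, p$enc[[4L]]))
  feat <- conv_fwd(a4, p$enc[[5L]])
  d1 <- lrelu(tconv_fwd(feat, p$dec[[1L]]))
  d2 <- lrelu(tconv_fwd(d1, p$dec[[2L]]))
  d2u <- rearrange(d2, cae$inv_orders)
  d3 <- lrelu(tconv_fwd(d2u, p$dec[[3L]]))
  d4 <- lrelu(tconv_fwd(d3, p$dec[[4L]]))
  recon <- tconv_fwd(d4, p$dec[[5L]])
  out <- list(feature = feat, recon = recon[, , 1L, , drop = TRUE])
  if (keep_cache) {
    out$cache <- list(x = x, a1 = a1, a2 = a2, a3r = a3r, a4 = a4,
                      feat = feat, d1 = d1, d2 = d2, d2u = d2u, d3 = d3,
                      d4 = d4, recon = recon)
  }
  out
}

# Fused single-precision forward/backward (see src/cae_core.cpp): the
# throughput path used by training, adaptation objectives and bulk
# evaluation. Agrees with the double-precision R path to float precision.
cae_fused <- function(cae, images, grads = TRUE, deep = TRUE,
                      want_recon = FALSE, want_feature = FALSE) {
  om <- do.call(rbind, cae$orders)
  x <- images
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  res <- .cae_fused_cpp(cae$params$enc, cae$params$dec, om, x, grads, deep,
                        want_recon, want_feature)
  if (grads) {
    eg <- res$enc_grads
    for (l in 1:3) {
      if (is.null(eg[[l]])) {
        eg[[l]] <- list(w = cae$params$enc[[l]]$w * 0,
                        b = cae$params$enc[[l]]$b * 0)
      }
    }
    res$grads <- list(enc = eg, dec = res$dec_grads)
  }
  res
}

# Rearranged stage-3 activations (after the temporal stack and the synergy
# rearrangement). Encoder layers 1-3 are frozen during online adaptation and
# meta-training, so this can be computed once and reused.
cae_stage3 <- function(cae, images) {
  p <- cae$params
  x <- as_image_batch(images)
  a1 <- lrelu(conv_fwd(x, p$enc[[1L]]))
  a2 <- lrelu(conv_fwd(a1, p$enc[[2L]]))
  a3 <- lrelu(conv_fwd(a2, p$enc[[3L]]))
  list(a3r = rearrange(a3, cae$orders), x = x)
}

# Forward from cached stage-3 activations; the cache it returns is the
# subset cae_backward needs for through_encoder = "stage4".
cae_forward_s3 <- function(cae, s3, keep_cache = FALSE) {
  p <- cae$params
  a4 <- lrelu(conv_fwd(s3$a3r, p$enc[[4L]]))
  feat <- conv_fwd(a4, p$enc[[5L]])
  d1 <- lrelu(tconv_fwd(feat, p$dec[[1L]]))
  d2 <- lrelu(tconv_fwd(d1, p$dec[[2L]]))
  d2u <- rearrange(d2, cae$inv_orders)
  d3 <- lrelu(tconv_fwd(d2u, p$dec[[3L]]))
  d4 <- lrelu(tconv_fwd(d3, p$dec[[4L]]))
  recon <- tconv_fwd(d4, p$dec[[5L]])
  out <- list(feature = feat, recon = recon[, , 1L, , drop = TRUE])
  if (keep_cache) {
    out$cache <- list(x = s3$x, a3r = s3$a3r, a4 = a4, feat = feat, d1 = d1,
                      d2 = d2, d2u = d2u, d3 = d3, d4 = d4, recon = recon)
  }
  out
}

# Gradients of a scalar loss w.r.t. all CAE parameters given the gradient at
# the reconstruction. `through_encoder` = "all" backpropagates the whole
# network, "stage4" stops after encoder layer 4 (enough for the online
# adaptation, whose tuned subset lives there).
cae_backward <- function(cae, cache, grecon, through_encoder = "all") {
  p <- cae$params
  g <- array(grecon, dim = dim(cache$recon))
  b5 <- tconv_bwd(cache$d4, p$dec[[5L]], g)
  g <- lrelu_bwd(b5$dx, cache$d4)
  b4 <- tconv_bwd(cache$d3, p$dec[[4L]], g)
  g <- lrelu_bwd(b4$dx, cache$d3)
  b3 <- tconv_bwd(cache$d2u, p$dec[[3L]], g)
  g <- rearrange(b3$dx, cae$orders) # adjoint of the inverse rearrangement
  g <- lrelu_bwd(g, cache$d2)
  b2 <- tconv_bwd(cache$d1, p$dec[[2L]], g)
  g <- lrelu_bwd(b2$dx, cache$d1)
  b1 <- tconv_bwd(cache$feat, p$dec[[1L]], g)
  gfeat <- b1$dx

  e5 <- conv_bwd(cache$a4, p$enc[[5L]], gfeat)
  g <- lrelu_bwd(e5$dx, cache$a4)
  deep <- through_encoder == "all"
  e4 <- conv_bwd(cache$a3r, p$enc[[4L]], g, need_dx = deep)
  enc_grads <- vector("list", 5L)
  enc_grads[[4L]] <- list(w = e4$dw, b = e4$db)
  enc_grads[[5L]] <- list(w = e5$dw, b = e5$db)
  if (deep) {
    g <- rearrange(e4$dx, cae$inv_orders) # adjoint of the rearrangement
    a3 <- rearrange(cache$a3r, cae$inv_orders)
    g <- lrelu_bwd(g, a3)
    e3 <- conv_bwd(cache$a2, p$enc[[3L]], g)
    g <- lrelu_bwd(e3$dx, cache$a2)
    e2 <- conv_bwd(cache$a1, p$enc[[2L]], g)
    g <- lrelu_bwd(e2$dx, cache$a1)
    e1 <- conv_bwd(cache$x, p$enc[[1L]], g, need_dx = FALSE)
    enc_grads[[1L]] <- list(w = e1$dw, b = e1$db)
    enc_grads[[2L]] <- list(w = e2$dw, b = e2$db)
    enc_grads[[3L]] <- list(w = e3$dw, b = e3$db)
  } else {
    for (l in 1:3) {
      enc_grads[[l]] <- list(w = p$enc[[l]]$w * 0, b = p$enc[[l]]$b * 0)
    }
  }
  list(enc = enc_grads,
       dec = list(list(w = b1$dw, b = b1$db), list(w = b2$dw, b = b2$db),
                  list(w = b3$dw, b = b3$db), list(w = b4$dw, b = b4$db),
                  list(w = b5$dw, b = b5$db)))
}

#' Encode sEMG images to the compressed feature
#'
#' @param cae a `cae` object.
#' @param images 9 x 200 matrix or 9 x 200 x B array of sEMG images.
#' @return The reshaped feature: a (B, 7, 120) array, time-major; feature
#'   index `40 * (row - 1) + map` is the frozen layout used by the
#'   prediction network.
#' @export
cae_encode <- function(cae, images) {
  feat <- cae_forward(cae, images)$feature
  feature_reshape(feat)
}

# (3, 7, 40, B) feature stack -> (B, 7, 120) time-major matrix sequence.
feature_reshape <- function(feat) {
  d <- dim(feat)
  out <- aperm(feat, c(4L, 2L, 3L, 1L))
  dim(out) <- c(d[4L], d[2L], d[3L] * d[1L])
  out
}

#' Reconstruct sEMG images through the autoencoder
#'
#' @param cae a `cae` object.
#' @param images 9 x 200 matrix or 9 x 200 x B array.
#' @return Reconstruction of the same shape, in original channel order.
#' @export
cae_reconstruct <- function(cae, images) {
  r <- cae_forward(cae, images)$recon
  if (length(dim(images)) == 2L) dim(r) <- dim(images)
  r
}

#' Total variance accounted for (tVAF)
#'
#' Reconstruction-fidelity metric comparing the sum of squared errors to the
#' total squared sum of the sEMG data over a whole image:
#' `1 - ||emg - recon||^2 / ||emg||^2` (Frobenius norms). Equal inputs give
#' 1, a zero reconstruction gives 0, and the value is invariant under
#' simultaneous scaling of both arguments.
#'
#' @param emg,recon arrays of identical shape; `emg` must not be all zero.
#' @return Fraction (can be negative for reconstructions worse than zero).
#' @export
tvaf <- function(emg, recon) {
  stopifnot(all(dim(emg) == dim(recon)) || length(emg) == length(recon))
  sst <- sum(emg^2)
  if (sst == 0) stop("tVAF undefined for an all-zero sEMG input")
  1 - sum((emg - recon)^2) / sst
}

# Per-image tVAF over a batch (9, 200, B).
tvaf_batch <- function(images, recons) {
  b <- dim(images)[3L]
  vapply(seq_len(b), function(i) tvaf(images[, , i], recons[, , i]),
         numeric(1))
}

#' Mean-squared reconstruction error of a batch
#'
#' The autoencoder training loss: the mean squared error between input
#' images and reconstructions (tVAF is the reporting metric, not the loss).
#'
#' @param images,recons 9 x 200 x B arrays.
#' @return Scalar mean squared error.
#' @export
reconstruction_loss <- function(images, recons) {
  if (length(images) == 0L) stop("empty batch")
  mean((images - recons)^2)
}

#' Train the convolutional autoencoder
#'
#' Minimizes the mean-squared reconstruction error with mini-batch SGD under
#' a step-decay learning-rate schedule.
#'
#' @param images 9 x 200 x N array of training sEMG images.
#' @param orders `channel_orders` for the synergy rearrangement.
#' @param epochs,batch_size,lr,lr_factor,lr_period SGD schedule; the
#'   full-scale reference schedule is 340 epochs, batch 100, lr 0.01
#'   multiplied by 0.8 every 40 epochs.
#' @param momentum classical momentum coefficient of the SGD updates.
#' @param optimizer `"sgd"` (the full-scale reference) or `"adam"` (used by
#'   the desk-scale configuration, where the step budget is far below the
#'   reference schedule's).
#' @param clip global-norm gradient clip (`Inf` = off); guards the high
#'   desk-scale learning rates against early loss spikes.
#' @param seed seed for initialization and batch shuffling.
#' @param verbose print per-epoch losses.
#' @return A trained `cae` object with an `history` vector of epoch losses.
#' @export
train_cae <- function(images, orders = NULL, epochs = 340L, batch_size = 100L,
                      lr = 0.01, lr_factor = 0.8, lr_period = 40L,
                      momentum = 0.9, optimizer = c("sgd", "adam"),
                      clip = Inf, seed = NULL, verbose = FALSE) {
  optimizer <- match.arg(optimizer)
  cae <- cae_init(orders, seed = seed)
  n <- dim(images)[3L]
  opt_state <- init_opt_state(optimizer, cae$params)
  with_seed(if (is.null(seed)) NULL else seed + 1L, {
    history <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      lr_ep <- lr_schedule(lr, lr_factor, lr_period, ep - 1L)
      ord <- sample.int(n)
      losses <- c()
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        batch <- images[, , idx, drop = FALSE]
        fb <- cae_fused(cae, batch)
        losses <- c(losses, fb$loss)
        grads <- fb$grads
        if (is.finite(clip)) grads <- clip_global_norm(grads, clip)
        upd <- apply_update(optimizer, cae$params, grads, opt_state, lr_ep,
                            momentum)
        cae$params <- upd$params
        opt_state <- upd$state
      }
      history[ep] <- mean(losses)
      if (verbose) {
        message(sprintf("epoch %d: loss %.5g (lr %.4g)", ep, history[ep], lr_ep))
      }
    }
    cae$history <- history
  })
  cae$trained <- TRUE
  cae
}

#' @export
print.cae <- function(x, ...) {
  cat("Convolutional autoencoder (9x200 sEMG image -> 40 x 3x7 feature)\n")
  cat(sprintf("  trained: %s", x$trained))
  if (!is.null(x$history)) {
    cat(sprintf(" (%d epochs, final reconstruction MSE %.4g)",
                length(x$history), x$history[length(x$history)]))
  }
  cat("\n")
  invisible(x)
}

#' @export
predict.cae <- function(object, images, type = c("feature", "reconstruction"),
                        ...) {
  type <- match.arg(type)
  if (type == "feature") cae_encode(object, images)
  else cae_reconstruct(object, images)
}
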