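# Motion prediction network: the 7x120 compressed sEMG feature passes
# per-time-step through FC1 (120 -> 100, ReLU) and FC2 (100 -> 1, ReLU); the
# resulting 7x1 series is concatenated with the 7x5 motion sequence and fed
# to three LSTM layers of 200 units; FC3 (200 -> 100, ReLU) and FC4
# (100 -> 1) read the final step's hidden state. One network instance per
# prediction target (each angle horizon, and the time-to-heel-strike event
# model); they share the architecture, never the weights. Features are plain
# inputs here, so prediction-loss gradients can never reach the autoencoder.

predictor_arch <- function() {
  list(fc1 = c(120L, 100L), fc2 = c(100L, 1L), lstm = c(6L, 200L, 3L),
       fc3 = c(200L, 100L), fc4 = c(100L, 1L))
}

#' Initialize a motion-prediction network
#'
#' @param task `"angle"` (future knee angle, degrees) or `"event"` (time to
#'   next heel strike, ms).
#' @param horizon look-ahead in IMU samples (angle task only).
#' @param seed initialization seed.
#' @return An object of class `intent_predictor`.
#' @export
predictor_init <- function(task = c("angle", "event"), horizon = NA_integer_,
                           seed = NULL) {
  task <- match.arg(task)
  a <- predictor_arch()
  params <- with_seed(seed, list(
    fc1 = init_dense_layer(a$fc1[1L], a$fc1[2L]),
    fc2 = init_dense_layer(a$fc2[1L], a$fc2[2L]),
    lstm = lstm_init(a$lstm[1L], a$lstm[2L], a$lstm[3L]),
    fc3 = init_dense_layer(a$fc3[1L], a$fc3[2L]),
    fc4 = init_dense_layer(a$fc4[1L], a$fc4[2L])))
  structure(list(params = params, task = task, horizon = horizon,
                 t_mean = 0, t_sd = 1, trained = FALSE, history = NULL),
            class = "intent_predictor")
}

# motions: (7, 5, B) array; features: (B, 7, 120) array from cae_encode().
# Output is in standardized target units; predict() un-standardizes.
predictor_forward <- function(pred, motions, features, keep_cache = FALSE) {
  B <- dim(features)[1L]
  fm <- matrix(features, B * 7L, 120L)
  h1 <- relu(dense_fwd(fm, pred$params$fc1))
  u <- relu(dense_fwd(h1, pred$params$fc2))
  x <- array(0, dim = c(B, 7L, 6L))
  x[, , 1L] <- matrix(u, B, 7L)
  x[, , 2:6] <- aperm(motions, c(3L, 1L, 2L))
  lf <- lstm_fwd(pred$params$lstm, x)
  hT <- matrix(lf$h[, 7L, ], B, 200L)
  h3 <- relu(dense_fwd(hT, pred$params$fc3))
  out <- dense_fwd(h3, pred$params$fc4)
  res <- list(out = out)
  if (keep_cache) {
    res$cache <- list(fm = fm, h1 = h1, u = u, x = x, lstm = lf, hT = hT,
                      h3 = h3, B = B)
  }
  res
}

predictor_backward <- function(pred, cache, gout) {
  p <- pred$params
  b4 <- dense_bwd(cache$h3, p$fc4, gout)
  g <- relu_bwd(b4$dx, cache$h3)
  b3 <- dense_bwd(cache$hT, p$fc3, g)
  gh <- array(0, dim = dim(cache$lstm$h))
  gh[, 7L, ] <- b3$dx
  bl <- lstm_bwd(p$lstm, cache$lstm$cache, gh_out = gh)
  gu <- matrix(bl$gx[, , 1L], cache$B * 7L, 1L)
  gu <- relu_bwd(gu, matrix(cache$u, cache$B * 7L, 1L))
  b2 <- dense_bwd(cache$h1, p$fc2, gu)
  g <- relu_bwd(b2$dx, cache$h1)
  b1 <- dense_bwd(cache$fm, p$fc1, g, need_dx = FALSE)
  list(fc1 = list(w = b1$dw, b = b1$db), fc2 = list(w = b2$dw, b = b2$db),
       lstm = bl$grads,
       fc3 = list(w = b3$dw, b = b3$db), fc4 = list(w = b4$dw, b = b4$db))
}

#' Mean-squared prediction error
#'
#' @param predictions,targets numeric vectors of matched length.
#' @return Scalar MSE.
#' @export
prediction_loss <- function(predictions, targets) {
  if (length(predictions) == 0L) stop("empty batch")
  if (length(predictions) != length(targets)) stop("length mismatch")
  mean((predictions - targets)^2)
}

#' Train a motion-prediction network
#'
#' Mini-batch SGD on the mean-squared prediction error with a step-decay
#' learning-rate schedule (full-scale reference: batch 100, lr 0.1 halved
#' every 40 epochs). Targets are z-scored from the training set during
#' optimization and un-standardized at prediction time, which conditions SGD
#' at the high reference learning rate.
#'
#' @param features (N, 7, 120) encoded sEMG features.
#' @param motions (7, 5, N) motion sequences.
#' @param targets length-N target vector (degrees or ms).
#' @param task,horizon stored metadata, see [predictor_init()].
#' @param epochs,batch_size,lr,lr_factor,lr_period SGD schedule.
#' @param momentum classical momentum coefficient of the SGD updates.
#' @param optimizer `"sgd"` (reference) or `"adam"` (desk scale).
#' @param seed seed for initialization and shuffling.
#' @param verbose print per-epoch losses.
#' @return A trained `intent_predictor`.
#' @export
train_predictor <- function(features, motions, targets,
                            task = c("angle", "event"),
                            horizon = NA_integer_, epochs = 60L,
                            batch_size = 100L, lr = 0.1, lr_factor = 0.5,
                            lr_period = 40L, momentum = 0.9,
                            optimizer = c("sgd", "adam"), seed = NULL,
                            verbose = FALSE) {
  task <- match.arg(task)
  optimizer <- match.arg(optimizer)
  pred <- predictor_init(task, horizon, seed = seed)
  pred$t_mean <- mean(targets)
  pred$t_sd <- stats::sd(targets)
  if (!is.finite(pred$t_sd) || pred$t_sd == 0) pred$t_sd <- 1
  tz <- (targets - pred$t_mean) / pred$t_sd
  n <- length(tz)
  opt_state <- init_opt_state(optimizer, pred$params)
  with_seed(if (is.null(seed)) NULL else seed + 1L, {
    history <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      lr_ep <- lr_schedule(lr, lr_factor, lr_period, ep - 1L)
      ord <- sample.int(n)
      losses <- c()
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        fw <- predictor_forward(pred, motions[, , idx, drop = FALSE],
                                features[idx, , , drop = FALSE],
                                keep_cache = TRUE)
        diff <- fw$out - tz[idx]
        losses <- c(losses, mean(diff^2))
        grads <- predictor_backward(pred, fw$cache,
                                    matrix(2 * diff / length(diff), ncol = 1L))
        upd <- apply_update(optimizer, pred$params, grads, opt_state, lr_ep,
                            momentum)
        pred$params <- upd$params
        opt_state <- upd$state
      }
      history[ep] <- mean(losses)
      if (verbose) {
        message(sprintf("epoch %d: loss %.5g (lr %.3g)", ep, history[ep], lr_ep))
      }
    }
    pred$history <- history
  })
  pred$trained <- TRUE
  pred
}

#' @export
predict.intent_predictor <- function(object, motions, features, ...) {
  out <- predictor_forward(object, motions, features)$out
  as.vector(out) * object$t_sd + object$t_mean
}

#' @export
print.intent_predictor <- function(x, ...) {
  lab <- if (x$task == "angle") {
    sprintf("knee angle, horizon %s IMU samples", x$horizon)
  } else "time to heel strike"
  cat(sprintf("Motion prediction network (%s); trained: %s\n", lab, x$trained))
  invisible(x)
}

#' Per-stride maximum prediction error
#'
#' Splits a predicted/label series into strides at the heel-strike indices
#' and reports the maximum absolute error inside each complete stride, the
#' standard stride-wise summary of trajectory-prediction accuracy.
#'
#' @param pred_series,label_series aligned numeric series.
#' @param strikes heel-strike indices (same index base as `t_index`).
#' @param t_index index of each series element on the heel-strike timeline;
#'   defaults to element position.
#' @return List with `per_stride` maximum absolute errors and their `mean`.
#' @export
max_stride_error <- function(pred_series, label_series, strikes,
                             t_index = seq_along(pred_series)) {
  stopifnot(length(pred_series) == length(label_series))
  if (length(strikes) < 2L) stop("need at least one complete stride")
  err <- abs(pred_series - label_series)
  stride <- findInterval(t_index, strikes)
  ok <- stride >= 1L & stride < length(strikes)
  if (!any(ok)) stop("no samples fall inside a complete stride")
  per <- tapply(err[ok], stride[ok], max)
  list(per_stride = as.numeric(per), mean = mean(per))
}
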