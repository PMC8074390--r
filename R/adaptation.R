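# Online adaptation by a learned optimizer: a small coordinatewise network
# (FC 3 -> 40 with Tanh, three LSTM layers of 40 units with per-coordinate
# recurrent state, FC 40 -> 1) maps each tuned parameter and its preprocessed
# gradient to a parameter increment, theta <- theta + g(grad_f, phi). Only
# two fixed parameter subsets are ever tuned online: the even input rows plus
# all biases of the prediction network's FC3 layer (10,100 coordinates), and
# every fourth input slice plus all biases of the encoder's fourth
# convolution layer (12,840 coordinates). The optimizer weights phi are
# shared across coordinates; only the recurrent state is per-coordinate.

#' Specification of an online-tunable parameter subset
#'
#' Describes which parameters of a network are adjusted online and in which
#' flattened order. The default predictor subset takes, per FC3 output node,
#' the 100 even-index input weights followed by the node's bias (so the flat
#' vector is the per-node 101-blocks concatenated over the 100 nodes); the
#' CAE subset takes the weights of every fourth input slice of encoder layer
#' 4 followed by all 40 biases. `fc3_all` and `fc4_all` are the comparative
#' variants tuning the full FC3 and FC4 layers.
#'
#' @param network `"predictor"` or `"cae"`.
#' @param variant `"default"`, `"fc3_all"` or `"fc4_all"` (predictor only).
#' @return An object of class `tuned_param_spec`.
#' @export
tuned_param_spec <- function(network = c("predictor", "cae"),
                             variant = c("default", "fc3_all", "fc4_all")) {
  network <- match.arg(network)
  variant <- match.arg(variant)
  if (network == "cae" && variant != "default") {
    stop("comparative variants exist for the predictor only")
  }
  structure(list(network = network, variant = variant),
            class = "tuned_param_spec")
}

#' Number of coordinates selected by a spec
#'
#' @param spec a `tuned_param_spec`.
#' @param model the network the spec refers to.
#' @return Integer coordinate count, derived from the actual parameter
#'   shapes.
#' @export
n_tuned <- function(spec, model) length(select_params(model, spec))

#' Gather the tuned parameters into a flat vector
#'
#' The inverse operation [scatter_params()] restores the values exactly;
#' parameters outside the subset are never touched.
#'
#' @param model an `intent_predictor` or `cae`.
#' @param spec a `tuned_param_spec`.
#' @return Numeric vector in the spec's flattening order.
#' @export
select_params <- function(model, spec) {
  stopifnot(inherits(spec, "tuned_param_spec"))
  if (spec$network == "predictor") {
    stopifnot(inherits(model, "intent_predictor"))
    if (spec$variant == "fc4_all") {
      lay <- model$params$fc4
      return(as.vector(rbind(lay$w, lay$b)))
    }
    lay <- model$params$fc3
    rows <- if (spec$variant == "fc3_all") seq_len(nrow(lay$w))
            else seq(2L, nrow(lay$w), by = 2L)
    # per output node: selected input weights then the node's bias
    as.vector(rbind(lay$w[rows, , drop = FALSE], lay$b))
  } else {
    stopifnot(inherits(model, "cae"))
    lay <- model$params$enc[[4L]]
    cin <- dim(lay$w)[3L]
    sel <- seq(4L, cin, by = 4L)
    c(as.vector(lay$w[, , sel, , drop = FALSE]), lay$b)
  }
}

#' Scatter a flat vector back into the tuned parameters
#'
#' @param model an `intent_predictor` or `cae`.
#' @param spec a `tuned_param_spec`.
#' @param values flat vector in the spec's flattening order.
#' @return The model with the subset overwritten.
#' @export
scatter_params <- function(model, spec, values) {
  stopifnot(inherits(spec, "tuned_param_spec"))
  if (spec$network == "predictor") {
    if (spec$variant == "fc4_all") {
      lay <- model$params$fc4
      m <- matrix(values, nrow(lay$w) + 1L, ncol(lay$w))
      model$params$fc4$w <- m[seq_len(nrow(lay$w)), , drop = FALSE]
      model$params$fc4$b <- m[nrow(lay$w) + 1L, ]
      return(model)
    }
    lay <- model$params$fc3
    rows <- if (spec$variant == "fc3_all") seq_len(nrow(lay$w))
            else seq(2L, nrow(lay$w), by = 2L)
    m <- matrix(values, length(rows) + 1L, ncol(lay$w))
    model$params$fc3$w[rows, ] <- m[seq_along(rows), , drop = FALSE]
    model$params$fc3$b <- m[length(rows) + 1L, ]
    model
  } else {
    lay <- model$params$enc[[4L]]
    d <- dim(lay$w)
    sel <- seq(4L, d[3L], by = 4L)
    nw <- 4L * 4L * length(sel) * d[4L]
    model$params$enc[[4L]]$w[, , sel, ] <-
      array(values[seq_len(nw)], dim = c(d[1L], d[2L], length(sel), d[4L]))
    model$params$enc[[4L]]$b <- values[nw + seq_len(d[4L])]
    model
  }
}

# Same gather/scatter applied to a gradient structure.
select_grads <- function(grads, spec) {
  if (spec$network == "predictor") {
    fake <- structure(list(params = grads), class = "intent_predictor")
  } else {
    fake <- structure(list(params = grads), class = "cae")
  }
  select_params(fake, spec)
}

#' Gradient preprocessing for the learned optimizer
#'
#' Rescales gradient magnitudes to a range a small network can ingest: a
#' coordinate with `|g| >= exp(-p)` maps to `(log(|g|)/p, sign(g))`, a
#' smaller one to `(-1, exp(p) * g)`. Both components are continuous at the
#' threshold and the first component is bounded above by `log(max|g|)/p`.
#'
#' @param g numeric gradient vector (must be finite).
#' @param p preprocessing constant.
#' @return n x 2 matrix of preprocessed pairs.
#' @export
preprocess_gradient <- function(g, p = 10) {
  if (any(!is.finite(g))) stop("non-finite gradient")
  big <- abs(g) >= exp(-p)
  cbind(ifelse(big, log(pmax(abs(g), .Machine$double.xmin)) / p, -1),
        ifelse(big, sign(g), exp(p) * g))
}

#' Initialize a learned optimizer
#'
#' The output layer starts at zero so an untrained optimizer proposes zero
#' increments; its weights move away from zero during meta-training.
#'
#' @param p gradient-preprocessing constant.
#' @param output_scale scaling of the network output into a parameter
#'   increment.
#' @param seed initialization seed.
#' @return An object of class `learned_optimizer`.
#' @export
optimizer_init <- function(p = 10, output_scale = 0.1, seed = NULL) {
  params <- with_seed(seed, {
    fc_in <- init_dense_layer(3L, 40L)
    lstm <- lstm_init(40L, 40L, 3L)
    list(fc_in = fc_in, lstm = lstm,
         fc_out = list(w = matrix(0, 40L, 1L), b = 0))
  })
  structure(list(params = params, p = p, output_scale = output_scale,
                 trained = FALSE, history = NULL),
            class = "learned_optimizer")
}

#' @export
print.learned_optimizer <- function(x, ...) {
  cat(sprintf("Coordinatewise learned optimizer (FC 3->40 + Tanh, 3x40 LSTM, FC 40->1); trained: %s\n",
              x$trained))
  invisible(x)
}

#' One step of the learned optimizer
#'
#' Applies the coordinatewise optimizer network to every tuned coordinate:
#' input `(theta_i, preprocessed gradient pair)`, output the increment
#' `delta_i`. The LSTM state is per-coordinate and persists across calls.
#'
#' @param opt a `learned_optimizer`.
#' @param theta current tuned-parameter vector.
#' @param grads gradient of the objective w.r.t. `theta` (same length).
#' @param state optional state from the previous call.
#' @param keep_cache retain intermediates for meta-training backprop.
#' @return List with `delta`, `theta_new = theta + delta`, `state`, and
#'   optionally `cache`.
#' @export
optimizer_step <- function(opt, theta, grads, state = NULL,
                           keep_cache = FALSE) {
  n <- length(theta)
  if (length(grads) != n) stop("theta/gradient length mismatch")
  if (!is.null(state) && nrow(state$h[[1L]]) != n) {
    stop("state does not match the number of tuned coordinates")
  }
  pre <- preprocess_gradient(grads, opt$p)
  inp <- cbind(theta, pre)
  z <- dense_fwd(inp, opt$params$fc_in)
  h0 <- tanh(z)
  x <- array(h0, dim = c(n, 1L, ncol(h0)))
  lf <- lstm_fwd(opt$params$lstm, x, state)
  hT <- matrix(lf$h[, 1L, ], n, dim(lf$h)[3L])
  out <- dense_fwd(hT, opt$params$fc_out)
  delta <- opt$output_scale * as.vector(out)
  res <- list(delta = delta, theta_new = theta + delta, state = lf$state)
  if (keep_cache) {
    res$cache <- list(inp = inp, h0 = h0, lstm = lf$cache, hT = hT, n = n)
  }
  res
}

# Backward through one optimizer step. gdelta: gradient w.r.t. delta;
# gstate: gradient w.r.t. the outgoing state (from later steps). Inputs
# (theta, preprocessed gradients) are treated as constants, the standard
# first-order truncation for learned-optimizer meta-training.
optimizer_step_bwd <- function(opt, cache, gdelta, gstate = NULL) {
  gout <- matrix(opt$output_scale * gdelta, ncol = 1L)
  bo <- dense_bwd(cache$hT, opt$params$fc_out, gout)
  gh <- array(bo$dx, dim = c(cache$n, 1L, ncol(cache$hT)))
  bl <- lstm_bwd(opt$params$lstm, cache$lstm, gh_out = gh, gstate = gstate)
  gz <- matrix(bl$gx, cache$n, ncol(cache$h0)) * (1 - cache$h0^2)
  bi <- dense_bwd(cache$inp, opt$params$fc_in, gz, need_dx = FALSE)
  list(grads = list(fc_in = list(w = bi$dw, b = bi$db), lstm = bl$grads,
                    fc_out = list(w = bo$dw, b = bo$db)),
       gstate0 = bl$gstate0)
}

clip_global_norm <- function(grads, max_norm) {
  flat2 <- function(g) if (is.list(g)) sum(vapply(g, flat2, numeric(1))) else sum(g^2)
  nrm <- sqrt(flat2(grads))
  if (is.finite(nrm) && nrm > max_norm) {
    scale_g <- function(g) if (is.list(g)) lapply(g, scale_g) else g * (max_norm / nrm)
    grads <- scale_g(grads)
  }
  grads
}

#' Meta-train a learned optimizer
#'
#' Trains the optimizer weights `phi` so that the increments it proposes
#' reduce a base network's loss. The base network stays frozen; per epoch,
#' one subject's batch is drawn, the tuned subset is unrolled through
#' `unroll` optimizer steps, and the meta-loss (mean base loss after each
#' step) is backpropagated into `phi` through the optimizer network only,
#' with the incoming gradients treated as constants (truncated first-order
#' unrolling). The tuned parameters are re-initialized to their trained
#' values every `reset_period` epochs. The full-scale reference schedule is
#' 550 epochs, lr 0.01 halved every 100 epochs, SGD batch 100.
#'
#' @param objective function(theta) -> list(loss, grad) evaluating the base
#'   network's loss and tuned-subset gradient on the current epoch's data;
#'   it is re-pointed at a new subject batch through `set_batch`.
#' @param theta0 trained values of the tuned subset.
#' @param set_batch function(epoch) selecting the subject batch for an
#'   epoch (called once per epoch; its return value is passed to
#'   `objective` as second argument).
#' @param epochs,lr,lr_factor,lr_period meta-training schedule.
#' @param unroll optimizer steps unrolled per epoch.
#' @param reset_period epochs between resets of the tuned parameters.
#' @param clip global-norm clip on the meta-gradient.
#' @param optimizer `"sgd"` (reference) or `"adam"` for the meta-updates of
#'   `phi`; the desk-scale configuration uses Adam, whose per-coordinate
#'   normalization reaches a useful increment scale within few meta-epochs.
#' @param p,output_scale,seed passed to [optimizer_init()].
#' @param verbose print per-epoch meta-losses.
#' @return A trained `learned_optimizer` with a `history` of meta-losses.
#' @export
train_optimizer <- function(objective, theta0, set_batch, epochs = 550L,
                            lr = 0.01, lr_factor = 0.5, lr_period = 100L,
                            unroll = 5L, reset_period = 10L, clip = 1,
                            optimizer = c("sgd", "adam"),
                            p = 10, output_scale = 0.1, seed = NULL,
                            verbose = FALSE) {
  optimizer <- match.arg(optimizer)
  opt <- optimizer_init(p = p, output_scale = output_scale, seed = seed)
  phi_state <- init_opt_state(optimizer, opt$params)
  theta <- theta0
  state <- NULL
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    if ((ep - 1L) %% reset_period == 0L) {
      theta <- theta0
      state <- NULL
    }
    batch <- set_batch(ep)
    caches <- vector("list", unroll)
    gs <- vector("list", unroll + 1L)
    losses <- numeric(unroll + 1L)
    for (t in seq_len(unroll)) {
      ob <- objective(theta, batch)
      losses[t] <- ob$loss
      gs[[t]] <- ob$grad
      st <- optimizer_step(opt, theta, ob$grad, state, keep_cache = TRUE)
      caches[[t]] <- st$cache
      theta <- st$theta_new
      state <- st$state
    }
    ob <- objective(theta, batch)
    losses[unroll + 1L] <- ob$loss
    gs[[unroll + 1L]] <- ob$grad
    history[ep] <- mean(losses[-1L]) # losses after each update

    # reverse pass: d meta / d delta_t = mean of later-step gradients
    phi_g <- NULL
    suffix <- gs[[unroll + 1L]]
    gstate <- NULL
    for (t in rev(seq_len(unroll))) {
      bw <- optimizer_step_bwd(opt, caches[[t]], suffix / unroll, gstate)
      phi_g <- if (is.null(phi_g)) bw$grads else accumulate_grads(phi_g, bw$grads)
      gstate <- bw$gstate0
      suffix <- suffix + gs[[t]]
    }
    phi_g <- clip_global_norm(phi_g, clip)
    lr_ep <- lr_schedule(lr, lr_factor, lr_period, ep - 1L)
    upd <- apply_update(optimizer, opt$params, phi_g, phi_state, lr_ep, 0.9)
    opt$params <- upd$params
    phi_state <- upd$state
    # state was produced by the old phi; detach across epochs
    if (verbose) message(sprintf("meta epoch %d: loss %.5g", ep, history[ep]))
  }
  opt$trained <- TRUE
  opt$history <- history
  opt
}

# Objective closure for meta-training / adapting the CAE: reconstruction MSE
# and its gradient w.r.t. the tuned encoder-layer-4 subset. Backpropagation
# stops after encoder layer 4 (layers 1-3 are frozen during adaptation).
make_cae_objective <- function(cae, spec) {
  force(cae); force(spec)
  function(theta, images) {
    model <- scatter_params(cae, spec, theta)
    fb <- cae_fused(model, images, grads = TRUE, deep = FALSE)
    list(loss = fb$loss, grad = select_grads(fb$grads, spec))
  }
}

# Objective closure for the prediction network: MSE in standardized target
# units and its gradient w.r.t. the tuned FC3 (or variant) subset. Batches
# carry pre-encoded features from the frozen CAE.
make_predictor_objective <- function(pred, spec) {
  force(pred); force(spec)
  function(theta, batch) {
    model <- scatter_params(pred, spec, theta)
    fw <- predictor_forward(model, batch$motions, batch$features,
                            keep_cache = TRUE)
    tz <- (batch$targets - pred$t_mean) / pred$t_sd
    diff <- fw$out - tz
    grads <- predictor_backward(model, fw$cache,
                                matrix(2 * diff / length(diff), ncol = 1L))
    list(loss = mean(diff^2), grad = select_grads(grads, spec))
  }
}

#' Online adaptation on a shifted data stream
#'
#' Mirrors the deployment protocol: one half of the shifted subject's data
#' provides the adaptation gradients, the other half measures the effect.
#' Per iteration the reconstruction-loss gradient of the CAE's tuned subset
#' and the prediction-loss gradient of the predictor's tuned subset are fed
#' to their respective learned optimizers, whose increments update the two
#' networks independently (the CAE is never touched by prediction error and
#' vice versa). Metrics on the held-out half are recorded before adaptation
#' and after every iteration.
#'
#' @param cae trained `cae`.
#' @param predictor trained `intent_predictor` (angle or event model).
#' @param opt_cae,opt_pred meta-trained `learned_optimizer`s (either may be
#'   `NULL` to leave that network fixed).
#' @param update_data,test_data `intent_dataset` halves of the shifted
#'   stream.
#' @param n_iter adaptation iterations (passes over the update half).
#' @param batch_size update mini-batch size within an iteration.
#' @param pred_spec,cae_spec tuned-parameter specs.
#' @return List with `before` and per-iteration `trace` metrics (`tvaf`,
#'   `pred_mse`, `max_stride_error`), plus the adapted networks.
#' @export
adapt_online <- function(cae, predictor, opt_cae, opt_pred, update_data,
                         test_data, n_iter = 1L, batch_size = 100L,
                         pred_spec = tuned_param_spec("predictor"),
                         cae_spec = tuned_param_spec("cae")) {
  if (!isTRUE(cae$trained) || !isTRUE(predictor$trained)) {
    stop("adaptation requires trained base networks")
  }
  if (dim(update_data$images)[3L] == 0L || dim(test_data$images)[3L] == 0L) {
    stop("empty update or test half")
  }

  target_of <- function(ds) {
    if (predictor$task == "event") ds$time_to_ic
    else ds$future_angles[, match(predictor$horizon, ds$horizons)]
  }
  eval_metrics <- function(cae_cur, pred_cur) {
    fw <- cae_fused(cae_cur, test_data$images, grads = FALSE,
                    want_recon = TRUE, want_feature = TRUE)
    recon <- array(fw$recon, dim = dim(test_data$images))
    feats <- feature_reshape(fw$feature)
    pr <- as.vector(predictor_forward(pred_cur, test_data$motions, feats)$out) *
      pred_cur$t_sd + pred_cur$t_mean
    lab <- target_of(test_data)
    mse <- max_err <- NA_real_
    mse <- mean((pr - lab)^2)
    max_err <- tryCatch(
      max_stride_error(pr, lab, test_data$heel_strikes,
                       t_index = test_data$t_end_imu)$mean,
      error = function(e) NA_real_)
    list(tvaf = mean(tvaf_batch(test_data$images, recon)),
         pred_mse = mse, max_stride_error = max_err,
         predictions = pr, labels = lab)
  }

  cae_cur <- cae
  pred_cur <- predictor
  before <- eval_metrics(cae_cur, pred_cur)
  theta_c <- select_params(cae_cur, cae_spec)
  theta_p <- select_params(pred_cur, pred_spec)
  state_c <- state_p <- NULL
  n_upd <- dim(update_data$images)[3L]
  starts <- seq(1L, n_upd, by = batch_size)
  upd_targets <- target_of(update_data)
  trace <- vector("list", n_iter)
  # one iteration = one pass over the update half in mini-batches; the
  # optimizers' per-coordinate LSTM state persists throughout
  for (it in seq_len(n_iter)) {
    for (st0 in starts) {
      idx <- st0:min(st0 + batch_size - 1L, n_upd)
      batch_imgs <- update_data$images[, , idx, drop = FALSE]
      if (!is.null(opt_cae)) {
        obj_c <- make_cae_objective(cae_cur, cae_spec)(theta_c, batch_imgs)
        st <- optimizer_step(opt_cae, theta_c, obj_c$grad, state_c)
        theta_c <- st$theta_new
        state_c <- st$state
        cae_cur <- scatter_params(cae_cur, cae_spec, theta_c)
      }
      if (!is.null(opt_pred)) {
        featsu <- feature_reshape(
          cae_fused(cae_cur, batch_imgs, grads = FALSE,
                    want_feature = TRUE)$feature)
        batch <- list(features = featsu,
                      motions = update_data$motions[, , idx, drop = FALSE],
                      targets = upd_targets[idx])
        obj_p <- make_predictor_objective(pred_cur, pred_spec)(theta_p, batch)
        st <- optimizer_step(opt_pred, theta_p, obj_p$grad, state_p)
        theta_p <- st$theta_new
        state_p <- st$state
        pred_cur <- scatter_params(pred_cur, pred_spec, theta_p)
      }
    }
    trace[[it]] <- eval_metrics(cae_cur, pred_cur)
  }
  list(before = before, trace = trace,
       after = if (n_iter > 0L) trace[[n_iter]] else before,
       cae = cae_cur, predictor = pred_cur)
}

#' Fraction of a shift-induced performance drop recovered by adaptation
#'
#' `(adapted - inter) / (intra - inter)`: 0 means no recovery, 1 means full
#' return to the unshifted level. Works for accuracy-like metrics (higher
#' better) and error metrics (lower better) alike.
#'
#' @param intra metric under matched train/test distribution.
#' @param inter metric under distribution shift, no adaptation.
#' @param adapted metric under shift after adaptation.
#' @return Scalar recovery fraction (as a proportion).
#' @export
relative_growth_rate <- function(intra, inter, adapted) {
  (adapted - inter) / (intra - inter)
}
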