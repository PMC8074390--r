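# Experimental protocol: leave-one-subject-out training on synthetic
# subjects, intra-/inter-subject evaluation, online adaptation of the
# held-out shifted subject, and metric aggregation.

#' Experiment configuration
#'
#' Bundles the generator settings, the training schedules of the three
#' networks, and the adaptation protocol. `scale = "paper"` carries the
#' full-scale reference schedules (42-min recordings with the first/last
#' minute discarded; CAE: SGD batch 100, 340 epochs, lr 0.01 x0.8 every 40;
#' predictor: lr 0.1 x0.5 every 40; optimizer: 550 epochs, lr 0.01 x0.5
#' every 100, tuned-parameter reset every 10). `scale = "desk"` shrinks
#' recording lengths, window counts and epoch numbers so the whole protocol
#' runs in minutes on one CPU while preserving every structural setting.
#'
#' @param scale `"desk"` or `"paper"`.
#' @param n_train_subjects training-group size (held-out subject is extra).
#' @param ... named overrides of individual fields.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(scale = c("desk", "paper"),
                              n_train_subjects = 8L, ...) {
  scale <- match.arg(scale)
  desk <- scale == "desk"
  cfg <- list(
    scale = scale,
    n_train_subjects = as.integer(n_train_subjects),
    duration = if (desk) 26 else 42 * 60,
    trim = if (desk) 1 else 60,
    cycle_period_mean = 1.1,
    cycle_period_cv = 0.03,
    # per-subject window budgets (subsampled evenly from each recording)
    windows_train = if (desk) 190L else Inf,
    windows_test = if (desk) 44L else Inf,
    predictor_samples = if (desk) 650L else Inf,
    nmf_decimation = 15L,
    # training group: long-session treadmill walking (spectra sit in the
    # fatigue-compressed band), per-subject global amplitude spread
    # (electrode impedance/placement) plus per-channel gain variability
    shift_train = list(gain = 1, global_gain_sd = 0.15, log_gain_sd = 0.20,
                       compression = c(0.65, 0.80), jitter = 0.05),
    # held-out subject: amplitude well below the training population and a
    # fresh (uncompressed) spectrum above the group's fatigue band
    shift_test = list(gain = 0.40, global_gain_sd = 0, log_gain_sd = 0,
                      compression = c(0.92, 1.0), jitter = 0.05),
    cae = list(epochs = if (desk) 12L else 340L, batch = if (desk) 8L else 100L,
               lr = if (desk) 0.001 else 0.01, lr_factor = 0.8,
               lr_period = 40L, optimizer = if (desk) "adam" else "sgd",
               clip = if (desk) 0.2 else Inf),
    predictor = list(epochs = if (desk) 14L else 340L,
                     batch = 100L,
                     lr = if (desk) 0.002 else 0.1, lr_factor = 0.5,
                     lr_period = 40L, optimizer = if (desk) "adam" else "sgd"),
    adaptation = list(epochs = if (desk) 22L else 550L,
                      lr = if (desk) 0.002 else 0.01,
                      lr_factor = 0.5, lr_period = 100L, reset_period = 10L,
                      unroll = if (desk) 4L else 10L,
                      meta_batch = if (desk) 24L else 100L,
                      adapt_batch = 100L,
                      optimizer = if (desk) "adam" else "sgd",
                      output_scale = 0.1, output_scale_cae = 0.01,
                      p = 10, clip = 1),
    horizons = c(1L, 5L, 10L, 15L),
    n_synergies = 5L,
    event_tol_ms = 6,
    n_adapt_iter = 1L)
  override <- list(...)
  for (nm in names(override)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(override[[nm]])) {
      utils::modifyList(cfg[[nm]], override[[nm]])
    } else override[[nm]]
  }
  structure(cfg, class = "experiment_config")
}

# Draw one synthetic subject's recording. Training-group subjects get mild
# per-channel gain/spectral variability; the held-out subject gets the
# stronger test shift.
make_subject_recording <- function(config, subject_id, role = c("train", "shifted"),
                                   seed) {
  role <- match.arg(role)
  sh <- if (role == "train") config$shift_train else config$shift_test
  subj_seed <- seed + 1000L * subject_id
  shift <- with_seed(subj_seed, {
    g0 <- sh$gain * exp(stats::rnorm(1, 0, sh$global_gain_sd))
    shift_params(amplitude_gain = g0 * exp(stats::rnorm(9, 0, sh$log_gain_sd)),
                 spectral_compression = stats::runif(1, sh$compression[1L], sh$compression[2L]),
                 envelope_jitter = sh$jitter)
  })
  params <- gait_params(duration = config$duration, seed = subj_seed + 1L,
                        cycle_period_mean = config$cycle_period_mean,
                        cycle_period_cv = config$cycle_period_cv,
                        n_synergies = config$n_synergies)
  rec <- generate_recording(params, shift)
  if (config$trim > 0) rec <- trim_recording(rec, config$trim, config$trim)
  rec
}

#' Generate the synthetic study population
#'
#' @param config an [experiment_config()].
#' @param seed base seed; each subject derives its own seed from it.
#' @return List with `train` (list of recordings) and `shifted` (one
#'   recording with the held-out distribution shift).
#' @export
make_subjects <- function(config, seed = 1L) {
  train <- lapply(seq_len(config$n_train_subjects), function(i) {
    make_subject_recording(config, i, "train", seed)
  })
  shifted <- make_subject_recording(config, config$n_train_subjects + 1L,
                                    "shifted", seed)
  list(train = train, shifted = shifted)
}

# Evenly subsample up to k window indices out of n.
even_subsample <- function(n, k) {
  if (!is.finite(k) || n <= k) seq_len(n) else unique(round(seq(1L, n, length.out = k)))
}

# Encode images through the CAE in chunks to bound memory.
encode_chunked <- function(cae, images, chunk = 200L) {
  n <- dim(images)[3L]
  out <- array(0, dim = c(n, 7L, 120L))
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    fw <- cae_fused(cae, images[, , idx, drop = FALSE], grads = FALSE,
                    want_feature = TRUE)
    out[idx, , ] <- feature_reshape(fw$feature)
  }
  out
}

# tVAF per image, chunked.
tvaf_chunked <- function(cae, images, chunk = 200L) {
  n <- dim(images)[3L]
  out <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    batch <- images[, , idx, drop = FALSE]
    fw <- cae_fused(cae, batch, grads = FALSE, want_recon = TRUE)
    out[idx] <- tvaf_batch(batch, array(fw$recon, dim = dim(batch)))
  }
  out
}

#' Fit the full motion-intention model on a training population
#'
#' Runs the three training stages in their required order: (1) muscle
#' synergies by NMF on the pooled rectified/low-pass-filtered training
#' envelopes, fixing the channel rearrangement; (2) the convolutional
#' autoencoder on pooled training windows; (3) one prediction network per
#' angle horizon plus the time-to-heel-strike model, fed by the frozen
#' encoder; (4) meta-training of the two learned optimizers on
#' subject-grouped batches. Later stages refuse untrained earlier stages.
#'
#' @param recordings list of training `gait_recording`s (one per subject).
#' @param config an [experiment_config()].
#' @param seed seed controlling subsampling, initialization and shuffling.
#' @param verbose print stage progress.
#' @return An object of class `intent_model`.
#' @export
fit_intent_model <- function(recordings, config = experiment_config(),
                             seed = 1L, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  n_sub <- length(recordings)
  if (n_sub < 2L) stop("need at least 2 training subjects")
  datasets <- lapply(recordings, build_dataset, horizons = config$horizons)

  # per-subject train/holdout window split (interleaved, then subsampled)
  splits <- lapply(datasets, function(ds) {
    n <- dim(ds$images)[3L]
    tr <- seq(1L, n, by = 2L)
    te <- seq(2L, n, by = 2L)
    list(train = tr[even_subsample(length(tr), config$windows_train)],
         test = te[even_subsample(length(te), config$windows_test)])
  })

  say("stage 1/4: muscle synergies (NMF)")
  V <- do.call(rbind, lapply(recordings, function(rec) {
    env <- semg_envelope(rec$semg, rec$rates$semg)
    t(env[, seq(1L, ncol(env), by = config$nmf_decimation), drop = FALSE])
  }))
  synergy <- fit_nmf(V, r = config$n_synergies, seed = seed)
  orders <- derive_channel_orders(synergy$H)

  say("stage 2/4: convolutional autoencoder")
  train_images <- do.call(abind3, lapply(seq_len(n_sub), function(s) {
    datasets[[s]]$images[, , splits[[s]]$train, drop = FALSE]
  }))
  cae <- train_cae(train_images, orders, epochs = config$cae$epochs,
                   batch_size = config$cae$batch, lr = config$cae$lr,
                   lr_factor = config$cae$lr_factor,
                   lr_period = config$cae$lr_period,
                   optimizer = config$cae$optimizer, clip = config$cae$clip,
                   seed = seed)

  say("stage 3/4: prediction networks")
  stopifnot(isTRUE(cae$trained))
  train_motions <- do.call(abind3m, lapply(seq_len(n_sub), function(s) {
    datasets[[s]]$motions[, , splits[[s]]$train, drop = FALSE]
  }))
  feats <- encode_chunked(cae, train_images)
  n_train <- dim(train_images)[3L]
  psel <- even_subsample(n_train, config$predictor_samples)
  pfeats <- feats[psel, , , drop = FALSE]
  pmots <- train_motions[, , psel, drop = FALSE]
  predictors <- list()
  for (h in config$horizons) {
    targets <- unlist(lapply(seq_len(n_sub), function(s) {
      datasets[[s]]$future_angles[splits[[s]]$train, match(h, config$horizons)]
    }))[psel]
    predictors[[paste0("angle", h)]] <-
      train_predictor(pfeats, pmots, targets, task = "angle",
                      horizon = h, epochs = config$predictor$epochs,
                      batch_size = config$predictor$batch,
                      lr = config$predictor$lr,
                      lr_factor = config$predictor$lr_factor,
                      lr_period = config$predictor$lr_period,
                      optimizer = config$predictor$optimizer,
                      seed = seed + h)
  }
  ev_targets <- unlist(lapply(seq_len(n_sub), function(s) {
    datasets[[s]]$time_to_ic[splits[[s]]$train]
  }))[psel]
  predictors$event <-
    train_predictor(pfeats, pmots, ev_targets, task = "event",
                    epochs = config$predictor$epochs,
                    batch_size = config$predictor$batch,
                    lr = config$predictor$lr,
                    lr_factor = config$predictor$lr_factor,
                    lr_period = config$predictor$lr_period,
                    optimizer = config$predictor$optimizer,
                    seed = seed + 99L)

  say("stage 4/4: learned optimizers (meta-training)")
  ad <- config$adaptation
  h_main <- config$horizons[length(config$horizons)]
  pred_main <- predictors[[paste0("angle", h_main)]]
  stopifnot(isTRUE(pred_main$trained))
  subj_of_train <- rep(seq_len(n_sub),
                       vapply(splits, function(s) length(s$train), integer(1)))
  meta_idx <- lapply(seq_len(n_sub), function(s) {
    cand <- which(subj_of_train == s)
    cand[even_subsample(length(cand), ad$meta_batch)]
  })
  # CAE optimizer: reconstruction loss, subject-grouped image batches
  cae_spec <- tuned_param_spec("cae")
  cae_batches <- lapply(meta_idx, function(idx) {
    train_images[, , idx, drop = FALSE]
  })
  subj_order <- with_seed(seed + 7L, {
    unlist(lapply(seq_len(ceiling(ad$epochs / n_sub)),
                  function(.) sample.int(n_sub)))
  })
  opt_cae <- train_optimizer(
    make_cae_objective(cae, cae_spec), select_params(cae, cae_spec),
    set_batch = function(ep) cae_batches[[subj_order[ep]]],
    epochs = ad$epochs, lr = ad$lr, lr_factor = ad$lr_factor,
    lr_period = ad$lr_period, unroll = ad$unroll,
    reset_period = ad$reset_period, clip = ad$clip,
    optimizer = ad$optimizer, p = ad$p,
    output_scale = ad$output_scale_cae, seed = seed + 11L)

  pred_spec <- tuned_param_spec("predictor")
  targets_main <- unlist(lapply(seq_len(n_sub), function(ss) {
    datasets[[ss]]$future_angles[splits[[ss]]$train,
                                 match(h_main, config$horizons)]
  }))
  pred_batches <- lapply(seq_len(n_sub), function(s) {
    idx <- meta_idx[[s]]
    list(features = feats[idx, , , drop = FALSE],
         motions = train_motions[, , idx, drop = FALSE],
         targets = targets_main[idx])
  })
  opt_pred <- train_optimizer(
    make_predictor_objective(pred_main, pred_spec),
    select_params(pred_main, pred_spec),
    set_batch = function(ep) pred_batches[[subj_order[ep]]],
    epochs = ad$epochs, lr = ad$lr, lr_factor = ad$lr_factor,
    lr_period = ad$lr_period, unroll = ad$unroll,
    reset_period = ad$reset_period, clip = ad$clip,
    optimizer = ad$optimizer, p = ad$p,
    output_scale = ad$output_scale, seed = seed + 13L)

  structure(list(synergy = synergy, orders = orders, cae = cae,
                 predictors = predictors, opt_cae = opt_cae,
                 opt_pred = opt_pred, config = config, seed = seed,
                 datasets = datasets, splits = splits),
            class = "intent_model")
}

abind3 <- function(...) {
  args <- list(...)
  d <- dim(args[[1L]])
  array(unlist(args, use.names = FALSE),
        dim = c(d[1L], d[2L], sum(vapply(args, function(a) dim(a)[3L], numeric(1)))))
}
abind3m <- abind3

#' @export
print.intent_model <- function(x, ...) {
  cat("Motion-intention model\n")
  cat(sprintf("  %d training subjects, horizons %s IMU samples + event model\n",
              length(x$datasets), paste(x$config$horizons, collapse = "/")))
  print(x$cae)
  invisible(x)
}

#' Evaluate a fitted model on a labeled dataset
#'
#' @param model an `intent_model`.
#' @param dataset an `intent_dataset`.
#' @return List with per-image `tvaf` (mean, sd), per-horizon stride-wise
#'   maximum angle errors, and event-prediction metrics (stride-wise
#'   time-to-heel-strike advance within tolerance).
#' @export
evaluate_intent_model <- function(model, dataset) {
  tv <- tvaf_chunked(model$cae, dataset$images)
  feats <- encode_chunked(model$cae, dataset$images)
  angle <- list()
  for (h in model$config$horizons) {
    pr <- predict(model$predictors[[paste0("angle", h)]], dataset$motions, feats)
    lab <- dataset$future_angles[, match(h, dataset$horizons)]
    mse <- max_stride_error(pr, lab, dataset$heel_strikes,
                            t_index = dataset$t_end_imu)
    angle[[paste0("h", h)]] <- list(max_err_mean = mse$mean,
                                    max_err_sd = stats::sd(mse$per_stride),
                                    per_stride = mse$per_stride)
  }
  ev_pred <- predict(model$predictors$event, dataset$motions, feats)
  adv <- event_advance(ev_pred, dataset$time_to_ic, dataset$heel_strikes,
                       tol_ms = model$config$event_tol_ms,
                       t_index = dataset$t_end_imu)
  list(tvaf = list(mean = mean(tv), sd = stats::sd(tv), per_image = tv),
       angle = angle,
       event = list(advance_mean = adv$mean, advance_sd = adv$sd,
                    per_stride = adv$per_stride,
                    predictions = ev_pred, labels = dataset$time_to_ic))
}

#' Predictable time-to-heel-strike advance
#'
#' Per stride, the largest true time-to-initial-contact T such that every
#' sample with label at most T is predicted within `tol_ms`; the summary of
#' how far ahead of the heel strike the event prediction is trustworthy.
#'
#' @param pred_series,label_series aligned predicted and true
#'   time-to-initial-contact series (ms).
#' @param strikes heel-strike indices on the `t_index` timeline.
#' @param tol_ms error tolerance (ms).
#' @param t_index index of each sample on the heel-strike timeline.
#' @return List with `per_stride` advances (ms; 0 when even the sample
#'   closest to the strike misses tolerance), their `mean` and `sd`.
#' @export
event_advance <- function(pred_series, label_series, strikes, tol_ms = 6,
                          t_index = seq_along(pred_series)) {
  stopifnot(length(pred_series) == length(label_series))
  if (length(strikes) < 2L) stop("need at least one complete stride")
  stride <- findInterval(t_index, strikes)
  ok_samples <- stride >= 1L & stride < length(strikes)
  if (!any(ok_samples)) stop("no samples fall inside a complete stride")
  err_ok <- abs(pred_series - label_series) <= tol_ms
  per <- tapply(seq_along(pred_series)[ok_samples], stride[ok_samples],
                function(ix) {
    lab <- label_series[ix]
    ok <- err_ok[ix]
    o <- order(lab)
    lab <- lab[o]; ok <- ok[o]
    bad <- which(!ok)
    if (length(bad) == 0L) max(lab)
    else if (bad[1L] == 1L) 0
    else lab[bad[1L] - 1L]
  })
  per <- as.numeric(per)
  list(per_stride = per, mean = mean(per), sd = stats::sd(per))
}

#' Compare adaptation variants on one shifted stream
#'
#' Runs [adapt_online()] once per tuned-parameter variant of the prediction
#' network (even FC3 rows, all FC3, all FC4) with the matching meta-trained
#' optimizer and logs the stride-wise maximum angle error per iteration.
#'
#' @param cae trained `cae`.
#' @param predictor trained angle `intent_predictor`.
#' @param optimizers named list of `learned_optimizer`s, one per variant
#'   (`default`, `fc3_all`, `fc4_all`).
#' @param update_data,test_data shifted-stream halves.
#' @param n_iter adaptation iterations.
#' @return Named list per variant with the per-iteration `max_err` curve and
#'   the `n_tuned` coordinate count.
#' @export
comparative_adaptation <- function(cae, predictor, optimizers, update_data,
                                   test_data, n_iter = 3L) {
  variants <- names(optimizers)
  bad <- setdiff(variants, c("default", "fc3_all", "fc4_all"))
  if (length(bad)) stop("unknown variant: ", paste(bad, collapse = ", "))
  out <- list()
  for (v in variants) {
    spec <- tuned_param_spec("predictor", v)
    res <- adapt_online(cae, predictor, opt_cae = NULL,
                        opt_pred = optimizers[[v]], update_data, test_data,
                        n_iter = n_iter, pred_spec = spec)
    out[[v]] <- list(
      max_err = vapply(res$trace, function(m) m$max_stride_error, numeric(1)),
      before = res$before$max_stride_error,
      n_tuned = n_tuned(spec, predictor))
  }
  out
}

#' Run the full synthetic study
#'
#' Generates the synthetic population, fits the model on the training group,
#' and reports intra-subject metrics (held-out windows of training
#' subjects), inter-subject metrics (the held-out shifted subject, no
#' adaptation), and post-adaptation metrics after `n_adapt_iter` learned
#' optimizer iterations using half of the shifted subject's data for
#' updates and the other half for testing.
#'
#' @param config an [experiment_config()].
#' @param seed master seed; every reported number is reproducible from
#'   (config, seed).
#' @param verbose print stage progress.
#' @return A report list: `tvaf` (intra/inter/adapted + recovery), `angle`
#'   (per-horizon intra errors, inter/adapted at the longest horizon),
#'   `event` (advance statistics), and the fitted `model`.
#' @export
run_experiment <- function(config = experiment_config(), seed = 1L,
                           verbose = FALSE) {
  subjects <- make_subjects(config, seed)
  model <- fit_intent_model(subjects$train, config, seed = seed,
                            verbose = verbose)

  # intra-subject: held-out windows of the training subjects
  n_sub <- length(model$datasets)
  intra_ds <- pool_datasets(lapply(seq_len(n_sub), function(s) {
    dataset_subset(model$datasets[[s]], model$splits[[s]]$test)
  }))
  intra <- evaluate_intent_model(model, intra_ds)

  # inter-subject: the shifted held-out subject, split into update/test
  shift_ds <- build_dataset(subjects$shifted, horizons = config$horizons)
  n_b <- dim(shift_ds$images)[3L]
  idx <- with_seed(seed + 23L, sample.int(n_b))
  upd_idx <- sort(idx[seq_len(n_b %/% 2L)])
  test_idx <- sort(idx[(n_b %/% 2L + 1L):n_b])
  test_idx <- test_idx[even_subsample(length(test_idx), 4L * config$windows_test)]
  upd_idx <- upd_idx[even_subsample(length(upd_idx), 4L * config$windows_train)]
  upd_ds <- dataset_subset(shift_ds, upd_idx)
  test_ds <- dataset_subset(shift_ds, test_idx)
  inter <- evaluate_intent_model(model, test_ds)

  h_main <- config$horizons[length(config$horizons)]
  pred_main <- model$predictors[[paste0("angle", h_main)]]
  ad <- adapt_online(model$cae, pred_main, model$opt_cae, model$opt_pred,
                     upd_ds, test_ds, n_iter = config$n_adapt_iter,
                     batch_size = config$adaptation$adapt_batch)

  tvaf_rep <- list(intra = intra$tvaf$mean, intra_sd = intra$tvaf$sd,
                   inter = inter$tvaf$mean, inter_sd = inter$tvaf$sd,
                   adapted = ad$after$tvaf,
                   recovery = relative_growth_rate(intra$tvaf$mean,
                                                   inter$tvaf$mean,
                                                   ad$after$tvaf))
  hkey <- paste0("h", h_main)
  angle_rep <- list(
    intra_max_err = vapply(intra$angle, function(a) a$max_err_mean, numeric(1)),
    intra_max_err_sd = vapply(intra$angle, function(a) a$max_err_sd, numeric(1)),
    inter_max_err = inter$angle[[hkey]]$max_err_mean,
    adapted_max_err = ad$after$max_stride_error,
    recovery = relative_growth_rate(intra$angle[[hkey]]$max_err_mean,
                                    inter$angle[[hkey]]$max_err_mean,
                                    ad$after$max_stride_error))
  list(tvaf = tvaf_rep, angle = angle_rep, event = intra$event,
       event_inter = inter$event, adaptation = ad, model = model,
       data = list(intra = intra_ds, update = upd_ds, test = test_ds),
       seed = seed)
}

# Concatenate several intent_datasets (heel-strike bookkeeping is kept
# per-sample via a synthetic stride id so stride-wise metrics stay valid
# across subject boundaries).
pool_datasets <- function(datasets) {
  out <- datasets[[1L]]
  out$images <- do.call(abind3, lapply(datasets, `[[`, "images"))
  out$motions <- do.call(abind3, lapply(datasets, `[[`, "motions"))
  out$time_to_ic <- unlist(lapply(datasets, `[[`, "time_to_ic"))
  out$future_angles <- do.call(rbind, lapply(datasets, `[[`, "future_angles"))
  # offset IMU indices and strikes so subjects occupy disjoint index ranges
  off <- 0L
  t_end <- integer(0); strikes <- integer(0)
  for (ds in datasets) {
    t_end <- c(t_end, ds$t_end_imu + off)
    strikes <- c(strikes, ds$heel_strikes + off)
    off <- off + max(ds$t_end_imu, ds$heel_strikes) + 1000L
  }
  out$t_end_imu <- t_end
  out$heel_strikes <- strikes
  out$t_end_semg <- NULL
  out
}
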