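test_that("the step-decay learning-rate schedule is exact", {
  # autoencoder reference schedule: x0.8 every 40 epochs
  expect_equal(sapply(c(0, 40, 80), function(e)
    semgintent:::lr_schedule(0.01, 0.8, 40, e)),
    0.01 * c(1, 0.8, 0.64))
  # the factor applies at, not after, the decay epoch boundary
  expect_equal(semgintent:::lr_schedule(0.01, 0.8, 40, 39), 0.01)
  expect_equal(semgintent:::lr_schedule(0.1, 0.5, 40, 40), 0.05)
})

test_that("event advance finds the horizon of trustworthy prediction", {
  # three strides of 30 IMU samples each (202.5 ms)
  strikes <- c(1L, 31L, 61L, 91L)
  t_index <- 1:90
  stride_pos <- (t_index - 1) %% 30
  label <- (30 - 1 - stride_pos) * 6.75 # time to next IC, ms
  label[t_index >= 61] <- (90 - t_index[t_index >= 61]) * 6.75

  exact <- event_advance(label, label, strikes, tol_ms = 6, t_index = t_index)
  expect_equal(exact$per_stride, rep(max(label[1:30]), 3))

  off <- event_advance(label + 10, label, strikes, tol_ms = 6,
                       t_index = t_index)
  expect_equal(off$per_stride, rep(0, 3))
  expect_equal(off$mean, 0)

  # prediction converges to the label 200 ms before IC: the advance is
  # 200 ms up to one IMU interval
  pred <- label + ifelse(label > 200, 25, 0)
  conv <- event_advance(pred, label, strikes, tol_ms = 6, t_index = t_index)
  expect_true(all(abs(conv$per_stride - 200) <= 6.75))
})

test_that("experiment configuration carries the reference schedules", {
  cfg <- experiment_config("paper")
  expect_equal(cfg$cae$epochs, 340L)
  expect_equal(cfg$cae$batch, 100L)
  expect_equal(cfg$cae$lr, 0.01)
  expect_equal(cfg$cae$lr_factor, 0.8)
  expect_equal(cfg$cae$lr_period, 40L)
  expect_equal(cfg$predictor$lr, 0.1)
  expect_equal(cfg$predictor$lr_factor, 0.5)
  expect_equal(cfg$adaptation$epochs, 550L)
  expect_equal(cfg$adaptation$lr, 0.01)
  expect_equal(cfg$adaptation$lr_period, 100L)
  expect_equal(cfg$adaptation$reset_period, 10L)
  expect_equal(cfg$horizons, c(1L, 5L, 10L, 15L))
  # desk scale preserves every structural setting
  desk <- experiment_config("desk")
  expect_equal(desk$adaptation$reset_period, 10L)
  expect_equal(desk$horizons, cfg$horizons)
  over <- experiment_config("desk", cae = list(epochs = 3L))
  expect_equal(over$cae$epochs, 3L)
  expect_equal(over$cae$lr_factor, 0.8)
})

test_that("comparative adaptation produces one aligned curve per variant", {
  tp <- fix_tiny_pipeline()
  opts <- list()
  for (v in c("default", "fc3_all", "fc4_all")) {
    o <- optimizer_init(seed = 7)
    o$trained <- TRUE
    o$params$fc_out$w[] <- 0.005
    opts[[v]] <- o
  }
  out <- comparative_adaptation(tp$cae, tp$pred, opts, tp$upd, tp$tst,
                                n_iter = 2)
  expect_named(out, c("default", "fc3_all", "fc4_all"))
  lens <- vapply(out, function(v) length(v$max_err), integer(1))
  expect_true(all(lens == 2L))
  expect_lt(out$default$n_tuned, out$fc3_all$n_tuned)
  expect_error(
    comparative_adaptation(tp$cae, tp$pred, list(bogus = opts[[1]]),
                           tp$upd, tp$tst), "unknown variant")
})
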