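test_that("tuned-parameter selection counts follow from the layer shapes", {
  pred <- predictor_init("angle", 15L, seed = 1)
  cae <- cae_init(seed = 1)
  spec_p <- tuned_param_spec("predictor")
  spec_c <- tuned_param_spec("cae")
  w3 <- pred$params$fc3$w
  # even input rows of the 200 x 100 matrix plus one bias per node
  expect_identical(n_tuned(spec_p, pred),
                   as.integer(ncol(w3) * (nrow(w3) / 2 + 1)))
  d4 <- dim(cae$params$enc[[4]]$w)
  expect_identical(n_tuned(spec_c, cae),
                   as.integer((d4[3] / 4) * d4[4] * d4[1] * d4[2] + d4[4]))
  # comparative variants
  expect_identical(n_tuned(tuned_param_spec("predictor", "fc3_all"), pred),
                   as.integer(ncol(w3) * (nrow(w3) + 1)))
  expect_identical(n_tuned(tuned_param_spec("predictor", "fc4_all"), pred),
                   as.integer(nrow(pred$params$fc4$w) + 1))
  expect_error(tuned_param_spec("cae", "fc4_all"), "predictor only")
})

test_that("the flat vector follows the per-node layout", {
  pred <- predictor_init("angle", 15L, seed = 2)
  spec <- tuned_param_spec("predictor")
  theta <- select_params(pred, spec)
  # node i occupies the 101-block [w_{2,i}, w_{4,i}, ..., w_{200,i}, b_i]
  for (i in c(1L, 57L, 100L)) {
    block <- theta[((i - 1) * 101 + 1):(i * 101)]
    expect_identical(block[1:100], pred$params$fc3$w[seq(2, 200, 2), i])
    expect_identical(block[101], pred$params$fc3$b[i])
  }
})

test_that("select/scatter round-trips losslessly and touches nothing else", {
  pred <- predictor_init("angle", 15L, seed = 3)
  cae <- cae_init(seed = 3)
  for (case in list(list(m = pred, s = tuned_param_spec("predictor")),
                    list(m = pred, s = tuned_param_spec("predictor", "fc3_all")),
                    list(m = pred, s = tuned_param_spec("predictor", "fc4_all")),
                    list(m = cae, s = tuned_param_spec("cae")))) {
    theta <- select_params(case$m, case$s)
    same <- scatter_params(case$m, case$s, theta)
    expect_identical(same$params, case$m$params)
    new <- scatter_params(case$m, case$s, theta + 1)
    expect_identical(select_params(new, case$s), theta + 1)
  }
  # untouched coordinates stay bit-identical
  spec <- tuned_param_spec("predictor")
  mod <- scatter_params(pred, spec, select_params(pred, spec) * 2)
  odd <- seq(1, 199, 2)
  expect_identical(mod$params$fc3$w[odd, ], pred$params$fc3$w[odd, ])
  expect_identical(mod$params$fc4, pred$params$fc4)
  expect_identical(mod$params$lstm, pred$params$lstm)
})

test_that("gradient preprocessing matches its two branches", {
  p <- 10
  expect_equal(preprocess_gradient(1, p), cbind(0, 1), ignore_attr = TRUE)
  expect_equal(preprocess_gradient(0, p), cbind(-1, 0), ignore_attr = TRUE)
  # continuity at the threshold: both branches give first component -1
  at <- preprocess_gradient(exp(-p), p)
  expect_equal(at[1], -1)
  expect_equal(at[2], 1)
  just_below <- preprocess_gradient(exp(-p) * (1 - 1e-12), p)
  expect_equal(just_below[1], -1)
  expect_equal(just_below[2], exp(p) * exp(-p), tolerance = 1e-6)
  # first component bounded by log(max|g|)/p
  set.seed(1)
  g <- rnorm(1000, 0, 10)
  pre <- preprocess_gradient(g, p)
  expect_lte(max(pre[, 1]), log(max(abs(g))) / p)
  expect_error(preprocess_gradient(c(1, NaN)), "non-finite")
})

test_that("an untrained optimizer proposes exactly zero increments", {
  opt <- optimizer_init(seed = 1) # zero output layer
  theta <- rnorm(500)
  g <- rnorm(500) * 1e-3
  st <- optimizer_step(opt, theta, g)
  expect_identical(st$delta, rep(0, 500))
  expect_identical(st$theta_new, theta)
  # deterministic given identical inputs and state
  opt$params$fc_out$w[] <- 0.01
  a <- optimizer_step(opt, theta, g)
  b <- optimizer_step(opt, theta, g)
  expect_identical(a$delta, b$delta)
  c2 <- optimizer_step(opt, theta, g, a$state)
  expect_false(identical(a$delta, c2$delta)) # state advances the LSTM
  expect_error(optimizer_step(opt, theta, g[-1]), "mismatch")
  expect_error(optimizer_step(opt, theta[-1], g[-1], a$state), "state")
})

test_that("optimizer output length matches both tuned subsets", {
  pred <- predictor_init("angle", 15L, seed = 4)
  cae <- cae_init(seed = 4)
  opt <- optimizer_init(seed = 4)
  for (case in list(list(m = pred, s = tuned_param_spec("predictor")),
                    list(m = cae, s = tuned_param_spec("cae")))) {
    theta <- select_params(case$m, case$s)
    st <- optimizer_step(opt, theta, theta * 1e-4)
    expect_length(st$delta, length(theta))
  }
})

test_that("meta-training teaches the optimizer to descend a simple objective", {
  # toy optimizee: quadratic bowls with per-episode random targets
  set.seed(10)
  n <- 60L
  make_target <- function(ep) rnorm(n, 0, 0.5)
  objective <- function(theta, target) {
    list(loss = mean((theta - target)^2), grad = 2 * (theta - target) / n)
  }
  theta0 <- rep(0, n)
  opt <- train_optimizer(objective, theta0, set_batch = make_target,
                         epochs = 120, lr = 0.01, lr_factor = 0.5,
                         lr_period = 60, unroll = 4, reset_period = 10,
                         seed = 11)
  expect_true(all(is.finite(opt$history)))
  # a trained optimizer reduces the loss of a fresh episode within one step
  target <- rnorm(n, 0, 0.5)
  ob <- objective(theta0, target)
  st <- optimizer_step(opt, theta0, ob$grad)
  expect_lt(objective(st$theta_new, target)$loss, ob$loss)
  # with zero meta-learning rate the tuned parameters never move
  opt0 <- train_optimizer(objective, theta0, set_batch = make_target,
                          epochs = 5, lr = 0, unroll = 2, reset_period = 10,
                          seed = 12)
  st0 <- optimizer_step(opt0, theta0, ob$grad)
  expect_identical(st0$theta_new, theta0)
})

test_that("adapting one network never touches the other", {
  tp <- fix_tiny_pipeline()
  cae <- tp$cae; pred <- tp$pred; upd <- tp$upd; tst <- tp$tst
  opt <- optimizer_init(seed = 3)
  opt$trained <- TRUE
  opt$params$fc_out$w[] <- 0.01 # nonzero increments

  only_cae <- adapt_online(cae, pred, opt_cae = opt, opt_pred = NULL,
                           upd, tst, n_iter = 1, batch_size = 30)
  expect_identical(only_cae$predictor$params, pred$params)
  expect_false(identical(only_cae$cae$params$enc[[4]], cae$params$enc[[4]]))
  # non-selected CAE parameters stay bit-identical
  expect_identical(only_cae$cae$params$enc[1:3], cae$params$enc[1:3])
  expect_identical(only_cae$cae$params$dec, cae$params$dec)
  sel <- seq(4, 80, by = 4)
  expect_identical(only_cae$cae$params$enc[[4]]$w[, , -sel, ],
                   cae$params$enc[[4]]$w[, , -sel, ])

  only_pred <- adapt_online(cae, pred, opt_cae = NULL, opt_pred = opt,
                            upd, tst, n_iter = 1, batch_size = 30)
  expect_identical(only_pred$cae$params, cae$params)
  expect_false(identical(only_pred$predictor$params$fc3, pred$params$fc3))
  odd <- seq(1, 199, 2)
  expect_identical(only_pred$predictor$params$fc3$w[odd, ],
                   pred$params$fc3$w[odd, ])
  expect_identical(only_pred$predictor$params$lstm, pred$params$lstm)

  # adaptation refuses untrained base networks
  expect_error(adapt_online(cae_init(seed = 9), pred, opt, NULL, upd, tst),
               "trained")
})

test_that("network checkpoints round-trip exactly", {
  tp <- fix_tiny_pipeline()
  opt <- optimizer_init(seed = 8)
  for (m in list(tp$cae, tp$pred, opt)) {
    f <- tempfile(fileext = ".rds")
    write_checkpoint(m, f)
    expect_identical(read_checkpoint(f), m)
    unlink(f)
  }
  f <- tempfile(fileext = ".rds")
  saveRDS(list(1, 2), f)
  expect_error(read_checkpoint(f), "checkpoint")
  unlink(f)
})
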