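test_that("the prediction network maps (motion, feature) to one finite scalar", {
  pred <- predictor_init("angle", horizon = 15L, seed = 1)
  set.seed(1)
  motions <- array(rnorm(7 * 5 * 3), c(7, 5, 3))
  feats <- array(rnorm(3 * 7 * 120), c(3, 7, 120))
  out <- predict(pred, motions, feats)
  expect_length(out, 3L)
  expect_true(all(is.finite(out)))
  # batch order does not matter
  perm <- c(2, 3, 1)
  expect_equal(predict(pred, motions[, , perm], feats[perm, , , drop = FALSE]),
               out[perm])
})

test_that("prediction loss is the mean squared error with its identities", {
  expect_equal(prediction_loss(1:5, 1:5), 0)
  set.seed(2)
  y <- rnorm(200)
  y <- y - mean(y)
  # constant predictor against centered targets: loss = target variance
  expect_equal(prediction_loss(rep(0, 200), y), mean(y^2))
  expect_error(prediction_loss(numeric(0), numeric(0)), "empty")
  expect_error(prediction_loss(1:3, 1:4), "mismatch")
})

test_that("predictor gradients match finite differences", {
  pred <- predictor_init("angle", horizon = 5L, seed = 3)
  set.seed(3)
  motions <- array(rnorm(7 * 5 * 2), c(7, 5, 2))
  feats <- array(rnorm(2 * 7 * 120), c(2, 7, 120))
  targets <- c(0.3, -0.8)
  loss_fn <- function(p) {
    out <- semgintent:::predictor_forward(p, motions, feats)$out
    mean((out - targets)^2)
  }
  fw <- semgintent:::predictor_forward(pred, motions, feats, keep_cache = TRUE)
  gr <- semgintent:::predictor_backward(
    pred, fw$cache, matrix(2 * (fw$out - targets) / 2, ncol = 1))
  eps <- 1e-5
  for (nm in c("fc1", "fc2", "fc3", "fc4")) {
    w <- pred$params[[nm]]$w
    for (i in sample(length(w), 2)) {
      up <- pred; up$params[[nm]]$w[i] <- w[i] + eps
      dn <- pred; dn$params[[nm]]$w[i] <- w[i] - eps
      expect_equal(gr[[nm]]$w[i], (loss_fn(up) - loss_fn(dn)) / (2 * eps),
                   tolerance = 1e-4)
    }
  }
  for (l in 1:3) {
    w <- pred$params$lstm[[l]]$wx
    for (i in sample(length(w), 2)) {
      up <- pred; up$params$lstm[[l]]$wx[i] <- w[i] + eps
      dn <- pred; dn$params$lstm[[l]]$wx[i] <- w[i] - eps
      expect_equal(gr$lstm[[l]]$wx[i], (loss_fn(up) - loss_fn(dn)) / (2 * eps),
                   tolerance = 1e-4)
    }
  }
})

test_that("stride-wise maximum error summarizes per-stride deviations", {
  strikes <- c(1L, 11L, 21L, 31L)
  t_index <- 1:30
  lab <- sin(1:30)
  expect_equal(max_stride_error(lab, lab, strikes, t_index)$per_stride,
               rep(0, 3))
  res <- max_stride_error(lab + 2, lab, strikes, t_index)
  expect_equal(res$per_stride, rep(2, 3))
  expect_equal(res$mean, 2)
  spiked <- lab
  spiked[15] <- lab[15] + 5
  res2 <- max_stride_error(spiked, lab, strikes, t_index)
  expect_equal(res2$per_stride, c(0, 5, 0))
  expect_error(max_stride_error(lab, lab, c(1L), t_index), "stride")
})

test_that("a small sample can be memorized by the prediction network", {
  ds <- fix_dataset()
  idx <- seq(1, dim(ds$images)[3], length.out = 20)
  cae <- cae_init(seed = 4)
  feats <- cae_encode(cae, ds$images[, , idx])
  motions <- ds$motions[, , idx]
  targets <- ds$future_angles[idx, 4]
  pred <- train_predictor(feats, motions, targets, task = "angle",
                          horizon = 15L, epochs = 500, batch_size = 20,
                          lr = 0.002, optimizer = "adam", seed = 5)
  # in standardized target units
  expect_lt(tail(pred$history, 1), 1e-2)
})
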