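test_that("encoder and decoder shapes follow the architecture exactly", {
  cae <- cae_init(seed = 1)
  x <- array(rnorm(9 * 200 * 2, 0, 0.2), c(9, 200, 2))
  fw <- semgintent:::cae_forward(cae, x, keep_cache = TRUE)
  cc <- fw$cache
  expect_equal(dim(cc$a1), c(9L, 96L, 20L, 2L))   # 200 - 105 + 1
  expect_equal(dim(cc$a2), c(9L, 42L, 40L, 2L))   # 96 - 55 + 1
  expect_equal(dim(cc$a3r), c(9L, 13L, 80L, 2L))  # 42 - 30 + 1
  expect_equal(dim(cc$a4), c(6L, 10L, 40L, 2L))   # 9-4+1, 13-4+1
  expect_equal(dim(cc$feat), c(3L, 7L, 40L, 2L))  # 6-4+1, 10-4+1
  expect_equal(dim(cc$recon), c(9L, 200L, 1L, 2L))
  expect_equal(dim(cae_encode(cae, x)), c(2L, 7L, 120L))
  expect_equal(dim(cae_reconstruct(cae, x[, , 1])), c(9L, 200L))
  # layer-4 parameter block is 80 x 40 x 4 x 4 weights + 40 biases
  expect_equal(dim(cae$params$enc[[4]]$w), c(4L, 4L, 80L, 40L))
  expect_equal(length(cae$params$enc[[4]]$b), 40L)
})

test_that("feature reshape layout is fixed and consistent", {
  cae <- cae_init(seed = 2)
  x <- array(rnorm(9 * 200 * 3, 0, 0.2), c(9, 200, 3))
  feat <- semgintent:::cae_forward(cae, x)$feature # (3, 7, 40, B)
  resh <- cae_encode(cae, x)                       # (B, 7, 120)
  for (b in 1:3) for (t in c(1, 4, 7)) for (i in 1:3) for (j in c(1, 17, 40)) {
    expect_identical(resh[b, t, 40 * (i - 1) + j], feat[i, t, j, b])
  }
})

test_that("tVAF matches its definition", {
  expect_equal(tvaf(matrix(1:6, 2), matrix(1:6, 2)), 1)
  expect_equal(tvaf(matrix(1:6, 2), matrix(0, 2, 3)), 0)
  expect_equal(tvaf(c(3, 4), c(3, 0)), 1 - 16 / 25)
  # invariant under simultaneous scaling; never above 1
  set.seed(1)
  e <- matrix(rnorm(40), 8); r <- matrix(rnorm(40), 8)
  expect_equal(tvaf(e, r), tvaf(3.7 * e, 3.7 * r))
  expect_lte(tvaf(e, r), 1)
  expect_error(tvaf(matrix(0, 2, 2), matrix(1, 2, 2)), "all-zero")
})

test_that("zero input with zero biases maps to zero everywhere", {
  cae <- cae_init(seed = 3) # biases initialize at zero
  x <- array(0, c(9, 200, 1))
  expect_true(all(cae_encode(cae, x) == 0))
  expect_true(all(cae_reconstruct(cae, x) == 0))
})

test_that("reconstruction loss is an order-invariant batch MSE", {
  set.seed(2)
  imgs <- array(rnorm(9 * 200 * 4), c(9, 200, 4))
  recs <- imgs + array(rnorm(9 * 200 * 4, 0, 0.1), c(9, 200, 4))
  expect_equal(reconstruction_loss(imgs, imgs), 0)
  perm <- c(3, 1, 4, 2)
  expect_equal(reconstruction_loss(imgs, recs),
               reconstruction_loss(imgs[, , perm], recs[, , perm]))
  expect_error(reconstruction_loss(array(0, c(9, 200, 0)),
                                   array(0, c(9, 200, 0))), "empty")
})

test_that("analytic gradients match finite differences through the whole CAE", {
  set.seed(5)
  img <- array(rnorm(9 * 200 * 2, 0, 0.2), c(9, 200, 2))
  orders <- structure(lapply(1:5, function(i) sample(9)),
                      class = "channel_orders")
  cae <- cae_init(orders, seed = 6)
  loss_fn <- function(model) {
    fw <- semgintent:::cae_forward(model, img, keep_cache = TRUE)
    mean((fw$cache$recon - fw$cache$x)^2)
  }
  fw <- semgintent:::cae_forward(cae, img, keep_cache = TRUE)
  gr <- semgintent:::cae_backward(cae, fw$cache,
                                  2 * (fw$cache$recon - fw$cache$x) /
                                    length(fw$cache$x))
  eps <- 1e-5
  for (part in c("enc", "dec")) for (l in c(1L, 3L, 4L, 5L)) {
    w <- cae$params[[part]][[l]]$w
    for (i in sample(length(w), 2)) {
      up <- cae; up$params[[part]][[l]]$w[i] <- w[i] + eps
      dn <- cae; dn$params[[part]][[l]]$w[i] <- w[i] - eps
      num <- (loss_fn(up) - loss_fn(dn)) / (2 * eps)
      expect_equal(gr[[part]][[l]]$w[i], num, tolerance = 1e-4)
    }
  }
})

test_that("single-precision fused pass agrees with the reference implementation", {
  set.seed(9)
  img <- array(rnorm(9 * 200 * 3, 0, 0.2), c(9, 200, 3))
  orders <- structure(lapply(1:5, function(i) sample(9)),
                      class = "channel_orders")
  cae <- cae_init(orders, seed = 10)
  fw <- semgintent:::cae_forward(cae, img, keep_cache = TRUE)
  gr <- semgintent:::cae_backward(cae, fw$cache,
                                  2 * (fw$cache$recon - fw$cache$x) /
                                    length(fw$cache$x))
  fb <- semgintent:::cae_fused(cae, img, grads = TRUE, want_recon = TRUE,
                               want_feature = TRUE)
  rel <- function(a, b) max(abs(a - b)) / max(abs(a))
  expect_lt(rel(array(fw$cache$recon, dim(img)), fb$recon), 1e-5)
  expect_lt(rel(fw$feature, fb$feature), 1e-5)
  for (part in c("enc", "dec")) for (l in 1:5) {
    expect_lt(rel(gr[[part]][[l]]$w, fb$grads[[part]][[l]]$w), 1e-3)
  }
})

test_that("training reduces the reconstruction loss on a small corpus", {
  ds <- fix_dataset()
  imgs <- ds$images[, , seq(1, dim(ds$images)[3], length.out = 40)]
  cae <- train_cae(imgs, epochs = 4, batch_size = 8, lr = 0.001,
                   optimizer = "adam", clip = 0.2, seed = 1)
  expect_lt(tail(cae$history, 1), cae$history[1])
  expect_true(cae$trained)
})

test_that("the autoencoder can overfit a single repeated image", {
  ds <- fix_dataset()
  img <- ds$images[, , 10, drop = FALSE]
  imgs <- img[, , rep(1, 8)]
  cae <- train_cae(imgs, epochs = 300, batch_size = 8, lr = 0.001,
                   optimizer = "adam", seed = 2)
  r <- cae_reconstruct(cae, img[, , 1])
  expect_gt(tvaf(img[, , 1], r), 0.99)
})
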