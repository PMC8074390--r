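test_that("NMF factorizes an exact low-rank matrix to high accuracy", {
  set.seed(4)
  V <- matrix(runif(200 * 5), 200, 5) %*% matrix(runif(5 * 9), 5, 9)
  fit <- fit_nmf(V, r = 5, seed = 5, max_iter = 20000, tol = 1e-10)
  expect_lt(fit$rel_error, 1e-3)
  expect_equal(dim(fit$W), c(200L, 5L))
  expect_equal(dim(fit$H), c(5L, 9L))
  expect_true(all(fit$W >= 0) && all(fit$H >= 0))
  # multiplicative updates never increase the Frobenius objective
  expect_true(all(diff(fit$objective) <= 1e-8 * fit$objective[1]))
})

test_that("NMF handles degenerate input structure", {
  set.seed(2)
  V <- matrix(runif(60 * 9), 60, 9)
  V[, 4] <- 0
  fit <- fit_nmf(V, r = 3, seed = 1)
  expect_true(all(abs(fit$H[, 4]) < 1e-10))
  expect_error(fit_nmf(V - 1, r = 3), "non-negative")
  expect_error(fit_nmf(V, r = 10), "exceed")
})

test_that("channel orders sort channels by descending synergy weight", {
  H <- matrix(0.01, 3, 9)
  H[1, 3] <- 1
  orders <- derive_channel_orders(H)
  expect_equal(orders[[1]], c(3L, 1L, 2L, 4:9))

  H2 <- rbind(seq(0.1, 0.9, length.out = 9))
  expect_equal(derive_channel_orders(H2)[[1]], 9:1)

  H3 <- matrix(rep(c(0.4, 0.2, 0.9), each = 9), 3, 9, byrow = TRUE) * 0 + 0.5
  o3 <- derive_channel_orders(H3)
  expect_identical(o3[[1]], o3[[2]])
  expect_identical(o3[[2]], o3[[3]])
  # every order is a bijection
  for (p in derive_channel_orders(matrix(runif(45), 5, 9))) {
    expect_setequal(p, 1:9)
  }
})

test_that("rearrange permutes channel axes group-wise and conserves totals", {
  set.seed(8)
  maps <- array(rnorm(9 * 13 * 80 * 2), c(9, 13, 80, 2))
  ident <- structure(rep(list(1:9), 5), class = "channel_orders")
  expect_identical(rearrange(maps, ident), maps)

  orders <- structure(lapply(1:5, function(i) sample(9)), class = "channel_orders")
  out <- rearrange(maps, orders)
  back <- rearrange(out, semgintent:::inverse_orders(orders))
  expect_identical(back, maps)
  # permutation conserves per-map channel sums
  expect_equal(apply(out, c(2, 3, 4), sum), apply(maps, c(2, 3, 4), sum))
  expect_error(rearrange(maps[, , 1:78, , drop = FALSE], orders), "divisible")
})

test_that("synergy similarity matches rows optimally", {
  set.seed(3)
  H <- matrix(runif(45), 5, 9)
  self <- synergy_similarity(H, H)
  expect_equal(self$matched, rep(1, 5), tolerance = 1e-12)
  expect_equal(self$matching, 1:5)

  # disjoint one-hot rows: best matching still has zero similarity
  A <- diag(1, 3, 9)
  B <- cbind(matrix(0, 3, 3), diag(1, 3, 6))[, 1:9]
  dis <- synergy_similarity(A, B)
  expect_equal(dis$matched, rep(0, 3))

  # permuted rows are recovered exactly
  perm <- c(3, 1, 4, 5, 2)
  sp <- synergy_similarity(H, H[perm, ])
  expect_equal(sp$mean, 1, tolerance = 1e-12)
  expect_equal(sp$matching, order(perm))
})

test_that("synergy models survive a text round-trip", {
  set.seed(1)
  V <- matrix(runif(60 * 9), 60, 9)
  fit <- fit_nmf(V, r = 3, seed = 1, max_iter = 50)
  dir <- tempfile("syn")
  write_synergy_model(fit, dir)
  back <- read_synergy_model(dir)
  expect_equal(back$H, fit$H, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$r, fit$r)
  unlink(dir, recursive = TRUE)
})
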