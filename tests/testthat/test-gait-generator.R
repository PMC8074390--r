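test_that("sample counts follow the sampling rates", {
  rec <- generate_recording(gait_params(duration = 10, seed = 1))
  expect_equal(ncol(rec$semg), round(10 * 1000 / 0.9))
  expect_equal(length(rec$angle), round(10 * 1000 / 6.75))
  # both streams cover the same wall-clock span within one IMU interval
  span_semg <- ncol(rec$semg) / rec$rates$semg
  span_imu <- length(rec$angle) / rec$rates$imu
  expect_lt(abs(span_semg - span_imu), 1 / rec$rates$imu)
})

test_that("generation is bit-reproducible and shift knobs act as documented", {
  p <- gait_params(duration = 8, seed = 7)
  a <- generate_recording(p)
  b <- generate_recording(p)
  expect_identical(a, b)

  g2 <- generate_recording(p, shift_params(amplitude_gain = 2))
  # same seed, doubled gain: every channel RMS exactly doubles
  expect_equal(apply(g2$semg, 1, stats::sd) / apply(a$semg, 1, stats::sd),
               rep(2, 9), tolerance = 1e-12, ignore_attr = TRUE)

  comp <- generate_recording(p, shift_params(spectral_compression = 0.7))
  cents_full <- sapply(1:3, function(c) spectral_centroid(a$semg[c, ], a$rates$semg))
  cents_comp <- sapply(1:3, function(c) spectral_centroid(comp$semg[c, ], a$rates$semg))
  expect_true(all(cents_comp < cents_full))
})

test_that("generator rejects invalid parameters", {
  expect_error(gait_params(duration = -1), "positive")
  expect_error(gait_params(duration = 2), "3 gait cycles")
  expect_error(gait_params(duration = 10, n_synergies = 12), "n_synergies")
  expect_error(shift_params(amplitude_gain = 0), "positive")
  expect_error(shift_params(spectral_compression = 1.5), "0, 1")
})

test_that("heel strikes are strictly increasing with realistic spacing", {
  rec <- generate_recording(gait_params(duration = 60, seed = 3,
                                        cycle_period_mean = 1.1))
  expect_true(all(diff(rec$heel_strikes) > 0))
  spacing <- mean(diff(rec$heel_strikes)) / rec$rates$imu
  expect_lt(abs(spacing - 1.1) / 1.1, 0.05)
})

test_that("activation envelopes have rank at most n_synergies", {
  rec <- fix_recording()
  sv <- svd(rec$envelopes)$d
  r <- rec$params$n_synergies
  expect_lt(sv[r + 1] / sv[1], 1e-8)
})

test_that("true_synergies exposes the generating factors", {
  p <- gait_params(duration = 8, seed = 5)
  ts <- true_synergies(p)
  expect_equal(dim(ts$H), c(5L, 9L))
  expect_equal(dim(ts$W), c(200L, 5L))
  expect_true(all(ts$H >= 0) && all(ts$W >= 0))

  # rank-1 structure: all channel envelopes proportional
  p1 <- gait_params(duration = 8, seed = 5, n_synergies = 1)
  rec1 <- generate_recording(p1)
  env <- rec1$envelopes
  cors <- stats::cor(t(env))
  expect_true(all(cors > 0.999))
})

test_that("NMF refit of generated envelopes recovers the synergy weights", {
  rec <- fixture("recording26", function() {
    generate_recording(gait_params(duration = 26, seed = 11))
  })
  env <- semg_envelope(rec$semg, rec$rates$semg)
  V <- t(env[, seq(1, ncol(env), by = 15)])
  fit <- fit_nmf(V, r = 5, seed = 2)
  sim <- synergy_similarity(true_synergies(rec$params)$H, fit$H)
  expect_gt(sim$mean, 0.9)
})

test_that("recordings survive a text round-trip", {
  rec <- fix_recording()
  dir <- tempfile("rec")
  write_recording(rec, dir)
  back <- read_recording(dir)
  expect_equal(back$semg, rec$semg, tolerance = 1e-6)
  expect_identical(back$heel_strikes, rec$heel_strikes)
  expect_equal(back$angle, rec$angle, tolerance = 1e-6)
  expect_equal(back$rates$semg, rec$rates$semg)
  unlink(dir, recursive = TRUE)
})
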