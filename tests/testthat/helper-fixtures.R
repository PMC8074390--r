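# Shared fixtures, built once per test run and cached in this environment.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# A short recording for structural tests (8 s keeps filtering fast).
fix_recording <- function() {
  fixture("recording8", function() {
    generate_recording(gait_params(duration = 8, seed = 42))
  })
}

fix_dataset <- function() {
  fixture("dataset8", function() build_dataset(fix_recording()))
}

# A minimal hand-built recording whose every stream is analytic, for exact
# label arithmetic.
toy_recording <- function(n_imu = 60L, strikes = c(11L, 31L, 51L),
                          angle = NULL) {
  n_semg <- round(n_imu * 7.5)
  structure(list(
    semg = matrix(stats::rnorm(9 * n_semg), 9,
                  dimnames = list(semg_channel_names(), NULL)),
    angle = if (is.null(angle)) seq_len(n_imu) else angle,
    thigh_w = numeric(n_imu), shank_w = numeric(n_imu),
    thigh_a = numeric(n_imu), shank_a = numeric(n_imu),
    heel_strikes = strikes,
    rates = list(semg = 1000 / 0.9, imu = 1000 / 6.75),
    duration = n_imu * 6.75 / 1000), class = "gait_recording")
}

num_grad <- function(f, x, eps = 1e-6) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# A minimally-trained CAE + predictor on the 8 s fixture, for structural
# adaptation/evaluation tests (not for accuracy assertions).
fix_tiny_pipeline <- function() {
  fixture("tiny_pipeline", function() {
    ds <- fix_dataset()
    n <- dim(ds$images)[3]
    sub <- semgintent:::dataset_subset(ds, seq(1, n, length.out = 60))
    upd <- semgintent:::dataset_subset(sub, seq(1, 60, 2))
    tst <- semgintent:::dataset_subset(sub, seq(2, 60, 2))
    cae <- train_cae(upd$images, epochs = 1, batch_size = 10, lr = 0.001,
                     optimizer = "adam", seed = 1)
    feats <- cae_encode(cae, upd$images)
    pred <- train_predictor(feats, upd$motions, upd$future_angles[, 4],
                            task = "angle", horizon = 15L, epochs = 2,
                            batch_size = 30, lr = 0.002, optimizer = "adam",
                            seed = 2)
    list(cae = cae, pred = pred, upd = upd, tst = tst)
  })
}
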