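#' Parameters of the synthetic gait-recording generator
#'
#' The generator emulates treadmill walking as captured by the assumed sensor
#' set: 9 sEMG channels sampled at 1111.111 Hz (0.9 ms interval), sagittal
#' thigh/shank motion channels plus a knee-angle channel at 148.148 Hz
#' (6.75 ms interval), and heel-strike events at gait-cycle onsets. Per-muscle
#' activation envelopes carry a low-rank muscle-synergy structure (rank
#' `n_synergies`) and multiply band-limited Gaussian carriers (20--450 Hz, the
#' usual surface-EMG band).
#'
#' @param duration recording length in seconds (must cover at least three
#'   gait cycles).
#' @param seed integer seed; one seeded generator drives all randomness of a
#'   generator call so equal parameters give bit-identical recordings.
#' @param n_channels number of sEMG channels (9 muscles).
#' @param semg_rate,imu_rate sampling rates in Hz. The defaults have sampling
#'   intervals of 0.9 ms and 6.75 ms whose least common multiple is 13.5 ms
#'   (15 sEMG samples = 2 IMU samples), the synchrony the segmentation relies
#'   on.
#' @param cycle_period_mean mean gait-cycle period in seconds.
#' @param cycle_period_cv coefficient of variation of the lognormal
#'   multiplicative cycle-period jitter.
#' @param n_synergies number of muscle synergies built into the activation
#'   envelopes; at most `n_channels`.
#' @return An object of class `gait_params`.
#' @export
gait_params <- function(duration = 30, seed = 1L, n_channels = 9L,
                        semg_rate = 1000 / 0.9, imu_rate = 1000 / 6.75,
                        cycle_period_mean = 1.1, cycle_period_cv = 0.03,
                        n_synergies = 5L) {
  if (duration <= 0 || semg_rate <= 0 || imu_rate <= 0) {
    stop("duration and sampling rates must be positive")
  }
  if (duration < 3 * cycle_period_mean) {
    stop("duration must cover at least 3 gait cycles")
  }
  if (n_synergies > n_channels) stop("n_synergies must not exceed n_channels")
  structure(list(duration = duration, seed = as.integer(seed),
                 n_channels = as.integer(n_channels),
                 semg_rate = semg_rate, imu_rate = imu_rate,
                 cycle_period_mean = cycle_period_mean,
                 cycle_period_cv = cycle_period_cv,
                 n_synergies = as.integer(n_synergies)),
            class = "gait_params")
}

#' Distribution-shift knobs of the gait generator
#'
#' Emulates the dominant modes of sEMG non-stationarity: under muscle fatigue
#' the sEMG amplitude rises while its frequency content shifts downwards, and
#' across subjects per-channel gains differ with electrode placement and
#' anatomy.
#'
#' @param amplitude_gain positive multiplicative gain, scalar or one value per
#'   channel.
#' @param spectral_compression fraction in (0, 1] scaling the carrier
#'   band edges; values below 1 move spectral content towards lower
#'   frequencies (fatigue direction).
#' @param envelope_jitter coefficient of variation of lognormal per-cycle
#'   envelope amplitude jitter.
#' @return An object of class `shift_params`.
#' @export
shift_params <- function(amplitude_gain = 1, spectral_compression = 1,
                         envelope_jitter = 0) {
  if (any(amplitude_gain <= 0)) stop("amplitude gains must be positive")
  if (spectral_compression <= 0 || spectral_compression > 1) {
    stop("spectral_compression must lie in (0, 1]")
  }
  if (envelope_jitter < 0) stop("envelope_jitter must be non-negative")
  structure(list(amplitude_gain = amplitude_gain,
                 spectral_compression = spectral_compression,
                 envelope_jitter = envelope_jitter),
            class = "shift_params")
}

#' @export
semg_channel_names <- function() {
  c("RF", "VM", "VL", "TA", "SOL", "SEM", "BF", "MG", "LG")
}

# Subject-level templates: synergy weights H (r x m), activation bump centers
# and widths over gait phase, knee/segment-angle templates. Drawn first in the
# generator's RNG stream so true_synergies() can reproduce them exactly.
gait_templates <- function(params) {
  r <- params$n_synergies
  m <- params$n_channels
  # canonical weights for the 9 muscles RF VM VL TA SOL SEM BF MG LG:
  # quadriceps (loading), plantarflexors (push-off), dorsiflexor (swing/IC),
  # hamstrings (late swing), hip-flexion burst (early swing)
  base <- rbind(
    c(0.90, 1.00, 0.95, 0.05, 0.02, 0.02, 0.05, 0.02, 0.02),
    c(0.02, 0.02, 0.02, 0.05, 1.00, 0.05, 0.05, 0.90, 0.85),
    c(0.10, 0.02, 0.02, 1.00, 0.02, 0.02, 0.05, 0.02, 0.02),
    c(0.05, 0.02, 0.02, 0.02, 0.05, 1.00, 0.90, 0.10, 0.10),
    c(0.80, 0.10, 0.10, 0.40, 0.02, 0.10, 0.05, 0.02, 0.02))
  centers0 <- c(0.08, 0.45, 0.95, 0.85, 0.65)
  widths0 <- c(0.08, 0.07, 0.10, 0.07, 0.08)
  if (r <= 5L) {
    base <- base[seq_len(r), , drop = FALSE]
    centers0 <- centers0[seq_len(r)]; widths0 <- widths0[seq_len(r)]
  } else {
    extra <- r - 5L
    base <- rbind(base, matrix(stats::runif(extra * 9, 0.02, 1), extra, 9))
    centers0 <- c(centers0, stats::runif(extra))
    widths0 <- c(widths0, rep(0.08, extra))
  }
  base <- base[, seq_len(m), drop = FALSE]
  H <- base * exp(matrix(stats::rnorm(r * m, 0, 0.15), r, m))
  centers <- (centers0 + stats::rnorm(r, 0, 0.02)) %% 1
  widths <- widths0 * exp(stats::rnorm(r, 0, 0.10))
  list(H = H, centers = centers, widths = widths)
}

# Gaussian bump on the circular gait phase in [0, 1).
phase_bump <- function(phase, center, width) {
  d <- (phase - center + 0.5) %% 1 - 0.5
  exp(-0.5 * (d / width)^2)
}

# Synergy activation patterns at given phases: length(phase) x r matrix, with
# a small tonic floor folded into the activations so the envelope matrix keeps
# rank <= r exactly.
synergy_activations <- function(tpl, phase) {
  r <- length(tpl$centers)
  out <- matrix(0, length(phase), r)
  for (k in seq_len(r)) {
    out[, k] <- phase_bump(phase, tpl$centers[k], tpl$widths[k]) + 0.05
  }
  out
}

# Two-bump knee-flexion profile over the gait cycle (degrees): a small
# loading-response flexion wave and a large swing flexion wave.
knee_template <- function(phase) {
  4 + 14 * phase_bump(phase, 0.15, 0.07) + 58 * phase_bump(phase, 0.73, 0.09)
}

thigh_template <- function(phase) 22 * sin(2 * pi * (phase + 0.08))

shank_template <- function(phase) {
  10 * sin(2 * pi * (phase + 0.02)) - 35 * phase_bump(phase, 0.78, 0.10)
}

#' Ground-truth synergy factors of a generator configuration
#'
#' Returns the synergy weights `H` and the activation patterns `W` (sampled on
#' a 200-point grid over one gait cycle) that the generator uses to build the
#' per-muscle activation envelopes; used as the reference in
#' parameter-recovery tests of the NMF fit.
#'
#' @param params a [gait_params()] object.
#' @return An object of class `synergy_model` with elements `W` (200 x r) and
#'   `H` (r x m).
#' @export
true_synergies <- function(params) {
  stopifnot(inherits(params, "gait_params"))
  tpl <- with_seed(params$seed, gait_templates(params))
  phase <- seq(0, 1, length.out = 201L)[-201L]
  W <- synergy_activations(tpl, phase)
  structure(list(W = W, H = tpl$H, r = params$n_synergies,
                 recon_error = 0, source = "generator"),
            class = "synergy_model")
}

# Stochastic sEMG carrier: Gaussian noise shaped in the frequency domain to
# the classic surface-EMG power spectrum P(f) ~ f^2 fh^4 / ((f^2 + fl^2)
# (f^2 + fh^2)^2) (corner frequencies fl = 60 Hz, fh = 120 Hz), restricted
# to the usual 15-450 Hz surface-EMG band. All frequencies scale with the
# spectral-compression knob, so compression < 1 moves the whole spectrum
# (and its centroid) downward, the fatigue direction. Unit variance.
semg_carrier <- function(n, rate, compression = 1) {
  x <- stats::rnorm(n)
  f <- (seq_len(n) - 1) * rate / n
  f <- pmin(f, rate - f) # two-sided frequency axis
  fl <- 60 * compression
  fh <- 120 * compression
  mag <- sqrt(f^2 * fh^4 / ((f^2 + fl^2) * (f^2 + fh^2)^2))
  mag[f < 15 * compression | f > 450 * compression] <- 0
  y <- Re(stats::fft(stats::fft(x) * mag, inverse = TRUE)) / n
  y / stats::sd(y)
}

#' Generate a synthetic gait recording
#'
#' Builds synchronized multi-rate streams: 9-channel sEMG whose per-muscle
#' envelope is the rank-`n_synergies` product of synergy activations and
#' weights multiplied by band-limited Gaussian carriers; smooth periodic knee
#' and segment kinematics phase-locked to heel strikes; and heel-strike
#' indices at cycle onsets. `shift` applies the distribution-shift knobs of
#' [shift_params()] on top of the same underlying random draws, so a shifted
#' and an unshifted call with the same seed differ only by the shift.
#'
#' @param params a [gait_params()] object.
#' @param shift a [shift_params()] object.
#' @return An object of class `gait_recording` with elements `semg`
#'   (channels x samples, mV), `angle`, `thigh_w`, `shank_w`, `thigh_a`,
#'   `shank_a` (IMU-rate series), `heel_strikes` (IMU sample indices),
#'   `envelopes` (ground-truth activation envelopes at sEMG rate) and `rates`.
#' @export
generate_recording <- function(params, shift = shift_params()) {
  stopifnot(inherits(params, "gait_params"), inherits(shift, "shift_params"))
  gains <- rep_len(shift$amplitude_gain, params$n_channels)
  with_seed(params$seed, {
    tpl <- gait_templates(params)

    # gait cycles: lognormal multiplicative period jitter
    n_cyc <- ceiling(params$duration / params$cycle_period_mean * 1.6) + 4L
    sdlog <- sqrt(log(1 + params$cycle_period_cv^2))
    periods <- params$cycle_period_mean *
      exp(stats::rnorm(n_cyc, -sdlog^2 / 2, sdlog))
    onsets <- cumsum(c(0, periods))

    n_semg <- round(params$duration * params$semg_rate)
    n_imu <- round(params$duration * params$imu_rate)
    t_semg <- (seq_len(n_semg) - 1) / params$semg_rate
    t_imu <- (seq_len(n_imu) - 1) / params$imu_rate

    phase_of <- function(tt) {
      k <- findInterval(tt, onsets)
      (tt - onsets[k]) / periods[k]
    }
    ph_semg <- phase_of(t_semg)
    ph_imu <- phase_of(t_imu)
    cyc_semg <- findInterval(t_semg, onsets)

    # envelopes: activations x weights, rank <= n_synergies by construction;
    # per-cycle jitter rescales columns and keeps the rank
    env <- synergy_activations(tpl, ph_semg) %*% tpl$H # n_semg x m
    jit <- exp(stats::rnorm(n_cyc, 0, 1))^shift$envelope_jitter
    env <- env * jit[cyc_semg]

    semg <- matrix(0, params$n_channels, n_semg,
                   dimnames = list(semg_channel_names()[seq_len(params$n_channels)], NULL))
    for (c in seq_len(params$n_channels)) {
      carrier <- semg_carrier(n_semg, params$semg_rate,
                              shift$spectral_compression)
      semg[c, ] <- gains[c] * 0.4 * env[, c] * carrier
    }

    angle <- knee_template(ph_imu) + stats::rnorm(n_imu, 0, 0.25)
    dt <- 1 / params$imu_rate
    deriv <- function(x) c(diff(x) / dt, 0)
    th <- thigh_template(ph_imu)
    sh <- shank_template(ph_imu)
    thigh_w <- deriv(th) + stats::rnorm(n_imu, 0, 2)
    shank_w <- deriv(sh) + stats::rnorm(n_imu, 0, 2)
    thigh_a <- deriv(deriv(th)) * pi / 180 * 0.4 + stats::rnorm(n_imu, 0, 0.2)
    shank_a <- deriv(deriv(sh)) * pi / 180 * 0.4 + stats::rnorm(n_imu, 0, 0.2)

    strikes <- round(onsets * params$imu_rate) + 1L
    strikes <- strikes[strikes >= 1L & strikes <= n_imu]

    structure(list(semg = semg, angle = angle,
                   thigh_w = thigh_w, shank_w = shank_w,
                   thigh_a = thigh_a, shank_a = shank_a,
                   heel_strikes = as.integer(strikes),
                   envelopes = t(env) * (gains * 0.4),
                   rates = list(semg = params$semg_rate, imu = params$imu_rate),
                   duration = params$duration, params = params, shift = shift),
              class = "gait_recording")
  })
}

#' @export
print.gait_recording <- function(x, ...) {
  cat("Synthetic gait recording\n")
  cat(sprintf("  duration: %.1f s, sEMG %d ch x %d samples @ %.3f Hz\n",
              x$duration, nrow(x$semg), ncol(x$semg), x$rates$semg))
  cat(sprintf("  motion/angle: %d samples @ %.3f Hz, %d heel strikes\n",
              length(x$angle), x$rates$imu, length(x$heel_strikes)))
  invisible(x)
}

#' Spectral centroid of a signal
#'
#' Mean frequency of the periodogram, used to verify that the generator's
#' spectral-compression knob moves sEMG content towards lower frequencies.
#'
#' @param x numeric signal.
#' @param rate sampling rate in Hz.
#' @return Centroid frequency in Hz.
#' @export
spectral_centroid <- function(x, rate) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = rate), plot = FALSE,
                          taper = 0, detrend = FALSE)
  sum(sp$freq * sp$spec) / sum(sp$spec)
}

#' Write/read a gait recording as a directory of delimited text files
#'
#' `semg.tsv` holds one column per muscle, `motion.tsv` the IMU-rate channels,
#' `heel_strikes.txt` the event indices, and `meta.dcf` the rates and channel
#' names.
#'
#' @param recording a `gait_recording`.
#' @param path directory to create/read.
#' @return `read_recording` returns a `gait_recording`.
#' @export
write_recording <- function(recording, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(t(recording$semg), file.path(path, "semg.tsv"),
                     sep = "\t", row.names = FALSE,
                     col.names = rownames(recording$semg))
  mot <- data.frame(angle = recording$angle, thigh_w = recording$thigh_w,
                    shank_w = recording$shank_w, thigh_a = recording$thigh_a,
                    shank_a = recording$shank_a)
  utils::write.table(mot, file.path(path, "motion.tsv"), sep = "\t",
                     row.names = FALSE)
  writeLines(as.character(recording$heel_strikes),
             file.path(path, "heel_strikes.txt"))
  write.dcf(data.frame(semg_rate = recording$rates$semg,
                       imu_rate = recording$rates$imu,
                       duration = recording$duration,
                       channels = paste(rownames(recording$semg), collapse = ",")),
            file.path(path, "meta.dcf"))
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  meta <- read.dcf(file.path(path, "meta.dcf"))
  semg <- t(as.matrix(utils::read.table(file.path(path, "semg.tsv"),
                                        sep = "\t", header = TRUE)))
  rownames(semg) <- strsplit(meta[1, "channels"], ",")[[1]]
  mot <- utils::read.table(file.path(path, "motion.tsv"), sep = "\t",
                           header = TRUE)
  structure(list(semg = semg, angle = mot$angle, thigh_w = mot$thigh_w,
                 shank_w = mot$shank_w, thigh_a = mot$thigh_a,
                 shank_a = mot$shank_a,
                 heel_strikes = as.integer(readLines(file.path(path, "heel_strikes.txt"))),
                 rates = list(semg = as.numeric(meta[1, "semg_rate"]),
                              imu = as.numeric(meta[1, "imu_rate"])),
                 duration = as.numeric(meta[1, "duration"])),
            class = "gait_recording")
}
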