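#' Segment the sEMG stream into sliding-window images
#'
#' Cuts each channel into windows of `window` samples (180 ms at the default
#' rate) advanced by `stride` samples (13.5 ms, the least common multiple of
#' the sEMG and IMU sampling intervals), and stacks the 9 channels of each
#' window into one sEMG image in the fixed muscle order RF, VM, VL, TA, SOL,
#' SEM, BF, MG, LG.
#'
#' @param recording a `gait_recording`.
#' @param window window length in sEMG samples.
#' @param stride window increment in sEMG samples.
#' @return List with `images`, a channels x window x n array (n = 0 when the
#'   recording is shorter than one window), and `t_end`, the 1-based index of
#'   each window's last sEMG sample.
#' @export
segment_semg <- function(recording, window = 200L, stride = 15L) {
  n <- ncol(recording$semg)
  ch <- nrow(recording$semg)
  if (n < window) {
    return(list(images = array(0, dim = c(ch, window, 0L)), t_end = integer(0)))
  }
  k <- (n - window) %/% stride + 1L
  starts <- (seq_len(k) - 1L) * stride + 1L
  images <- array(0, dim = c(ch, window, k))
  for (i in seq_len(k)) {
    images[, , i] <- recording$semg[, starts[i]:(starts[i] + window - 1L)]
  }
  list(images = images, t_end = starts + window - 1L)
}

# IMU-rate motion matrix in the fixed column order
# [knee angle, thigh omega, shank omega, thigh accel, shank accel].
motion_matrix <- function(recording) {
  cbind(angle = recording$angle, thigh_w = recording$thigh_w,
        shank_w = recording$shank_w, thigh_a = recording$thigh_a,
        shank_a = recording$shank_a)
}

#' Segment the motion channels into overlapping sequences
#'
#' Cuts the IMU-rate motion matrix into blocks of `length` consecutive
#' samples (87.75 ms) advanced by `stride` samples (13.5 ms), then decimates
#' each 13-sample block by two (samples 1, 3, ..., 13) to the 7 x 5 motion
#' sequence consumed by the prediction network; the decimation keeps the
#' 87.75 ms span.
#'
#' @param recording a `gait_recording`.
#' @param length block length in IMU samples.
#' @param stride block increment in IMU samples.
#' @return List with `blocks` (length x 5 x n), `sequences` (7 x 5 x n after
#'   decimation) and `t_end` (1-based IMU index of each block's last sample).
#' @export
segment_motion <- function(recording, length = 13L, stride = 2L) {
  mm <- motion_matrix(recording)
  n <- nrow(mm)
  if (n < length) {
    return(list(blocks = array(0, dim = c(length, 5L, 0L)),
                sequences = array(0, dim = c((length + 1L) %/% 2L, 5L, 0L)),
                t_end = integer(0)))
  }
  k <- (n - length) %/% stride + 1L
  starts <- (seq_len(k) - 1L) * stride + 1L
  blocks <- array(0, dim = c(length, 5L, k))
  for (i in seq_len(k)) {
    blocks[, , i] <- mm[starts[i]:(starts[i] + length - 1L), ]
  }
  keep <- seq(1L, length, by = 2L)
  list(blocks = blocks,
       sequences = blocks[keep, , , drop = FALSE],
       t_end = starts + length - 1L)
}

#' Time to the next heel strike for every IMU sample
#'
#' @param recording a `gait_recording`.
#' @return Numeric vector (ms) per IMU sample; a sample lying on a strike maps
#'   to 0, and samples after the last recorded strike are `NA` (they carry no
#'   label and are dropped downstream).
#' @export
label_time_to_ic <- function(recording) {
  n <- length(recording$angle)
  strikes <- recording$heel_strikes
  idx <- seq_len(n)
  pos <- findInterval(idx - 1L, strikes) + 1L # first strike >= idx
  nxt <- ifelse(pos <= length(strikes), strikes[pos], NA_integer_)
  (nxt - idx) * 1000 / recording$rates$imu
}

#' Future knee angle at a fixed horizon
#'
#' @param recording a `gait_recording`.
#' @param horizon_samples look-ahead in IMU samples (1, 5, 10 and 15 samples
#'   correspond to 6.75, 33.75, 67.5 and 101.25 ms at the default rate).
#' @return Numeric vector per IMU sample: the knee angle `horizon_samples`
#'   later, `NA` where the horizon exceeds the recording.
#' @export
label_future_angle <- function(recording, horizon_samples) {
  n <- length(recording$angle)
  tgt <- seq_len(n) + horizon_samples
  out <- rep(NA_real_, n)
  ok <- tgt >= 1L & tgt <= n
  out[ok] <- recording$angle[tgt[ok]]
  out
}

#' Discard unsteady head and tail of a recording
#'
#' Removes the first `head` and last `tail` seconds from every stream
#' consistently (heel-strike indices are shifted accordingly), mirroring the
#' practice of discarding the acceleration and deceleration phases of a
#' treadmill session.
#'
#' @param recording a `gait_recording`.
#' @param head,tail seconds to drop at each end.
#' @return The trimmed `gait_recording`.
#' @export
trim_recording <- function(recording, head = 60, tail = 60) {
  if (recording$duration <= head + tail) {
    stop("recording shorter than head + tail")
  }
  n_semg_head <- round(head * recording$rates$semg)
  n_semg_tail <- round(tail * recording$rates$semg)
  n_imu_head <- round(head * recording$rates$imu)
  n_imu_tail <- round(tail * recording$rates$imu)
  keep_semg <- (n_semg_head + 1L):(ncol(recording$semg) - n_semg_tail)
  keep_imu <- (n_imu_head + 1L):(length(recording$angle) - n_imu_tail)
  out <- recording
  out$semg <- recording$semg[, keep_semg, drop = FALSE]
  for (nm in c("angle", "thigh_w", "shank_w", "thigh_a", "shank_a")) {
    out[[nm]] <- recording[[nm]][keep_imu]
  }
  if (!is.null(recording$envelopes)) {
    out$envelopes <- recording$envelopes[, keep_semg, drop = FALSE]
  }
  hs <- as.integer(recording$heel_strikes - n_imu_head)
  out$heel_strikes <- hs[hs >= 1L & hs <= length(keep_imu)]
  out$duration <- recording$duration - head - tail
  out
}

#' Build the labeled (sEMG image, motion sequence, targets) dataset
#'
#' Segments both streams, pairs each sEMG image with the motion sequence
#' whose end lies closest in wall-clock time (both segmentations advance by
#' 13.5 ms, so ends of paired segments agree within one IMU interval), and
#' labels each pair at the motion sequence's final IMU sample with the time
#' to the next heel strike and with future knee angles at the requested
#' horizons. Pairs whose labels fall outside the recording are dropped.
#'
#' @param recording a `gait_recording`.
#' @param horizons look-ahead horizons in IMU samples.
#' @return An object of class `intent_dataset`: `images` (9 x 200 x n),
#'   `motions` (7 x 5 x n), `time_to_ic` (ms), `future_angles` (n x length(horizons)),
#'   `t_end_semg`, `t_end_imu`, `horizons`.
#' @export
build_dataset <- function(recording, horizons = c(1L, 5L, 10L, 15L)) {
  seg_s <- segment_semg(recording)
  seg_m <- segment_motion(recording)
  dt_semg <- 1000 / recording$rates$semg
  dt_imu <- 1000 / recording$rates$imu
  end_ms_img <- (seg_s$t_end - 1L) * dt_semg
  end_ms_mot <- (seg_m$t_end - 1L) * dt_imu
  # both sequences advance 13.5 ms per step: constant index offset
  stride_ms <- 13.5
  off <- round((end_ms_img[1L] - end_ms_mot[1L]) / stride_ms)
  j <- seq_along(seg_s$t_end) + off
  ok <- j >= 1L & j <= length(seg_m$t_end)
  i <- which(ok); j <- j[ok]

  tti_all <- label_time_to_ic(recording)
  ang <- lapply(horizons, function(h) label_future_angle(recording, h))
  t_imu <- seg_m$t_end[j]
  labels <- cbind(tti_all[t_imu],
                  do.call(cbind, lapply(ang, function(a) a[t_imu])))
  keep <- stats::complete.cases(labels)
  i <- i[keep]; j <- j[keep]
  fa <- labels[keep, -1L, drop = FALSE]
  colnames(fa) <- paste0(round(horizons * dt_imu, 2), "ms")
  structure(list(images = seg_s$images[, , i, drop = FALSE],
                 motions = seg_m$sequences[, , j, drop = FALSE],
                 time_to_ic = labels[keep, 1L],
                 future_angles = fa,
                 t_end_semg = seg_s$t_end[i],
                 t_end_imu = seg_m$t_end[j],
                 horizons = horizons,
                 rates = recording$rates,
                 heel_strikes = recording$heel_strikes),
            class = "intent_dataset")
}

#' @export
print.intent_dataset <- function(x, ...) {
  cat(sprintf("intent_dataset: %d labeled samples, horizons %s IMU samples\n",
              dim(x$images)[3L], paste(x$horizons, collapse = "/")))
  invisible(x)
}

# Subset an intent_dataset by sample index.
dataset_subset <- function(dataset, idx) {
  out <- dataset
  out$images <- dataset$images[, , idx, drop = FALSE]
  out$motions <- dataset$motions[, , idx, drop = FALSE]
  out$time_to_ic <- dataset$time_to_ic[idx]
  out$future_angles <- dataset$future_angles[idx, , drop = FALSE]
  out$t_end_semg <- dataset$t_end_semg[idx]
  out$t_end_imu <- dataset$t_end_imu[idx]
  out
}
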