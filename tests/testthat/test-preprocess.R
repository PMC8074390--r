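test_that("sEMG segmentation matches the closed-form window count", {
  rec <- toy_recording(n_imu = 40L)
  # exactly one window at the boundary
  rec1 <- rec; rec1$semg <- rec$semg[, 1:200]
  expect_equal(dim(segment_semg(rec1)$images), c(9L, 200L, 1L))
  # 230 samples: starts 1, 16, 31
  rec2 <- rec; rec2$semg <- rec$semg[, 1:230]
  seg <- segment_semg(rec2)
  expect_equal(dim(seg$images)[3], 3L)
  expect_equal(seg$t_end, c(200L, 215L, 230L))
  expect_equal(seg$images[, , 2], unname(rec$semg[, 16:215]))
  # shorter than one window: empty output, not an error
  rec3 <- rec; rec3$semg <- rec$semg[, 1:150]
  expect_equal(dim(segment_semg(rec3)$images)[3], 0L)
})

test_that("window counts obey floor((n - window)/stride) + 1 (enumeration)", {
  for (n in c(200L, 207L, 215L, 260L, 395L)) {
    rec <- toy_recording(n_imu = 60L)
    rec$semg <- rec$semg[, seq_len(n)]
    for (stride in c(5L, 15L)) {
      got <- dim(segment_semg(rec, stride = stride)$images)[3]
      brute <- sum(sapply(seq_len(n), function(s) {
        (s - 1) %% stride == 0 && s + 200L - 1L <= n
      }))
      expect_identical(got, as.integer(brute))
      expect_identical(got, as.integer((n - 200L) %/% stride + 1L))
    }
  }
})

test_that("motion segmentation yields decimated 7x5 sequences", {
  rec <- toy_recording(n_imu = 13L, strikes = c(1L, 10L))
  seg <- segment_motion(rec)
  expect_equal(dim(seg$blocks), c(13L, 5L, 1L))
  expect_equal(dim(seg$sequences), c(7L, 5L, 1L))
  # decimation keeps samples 1,3,...,13 so the 87.75 ms span is preserved
  expect_equal(seg$sequences[, 1, 1], rec$angle[seq(1, 13, by = 2)])

  rec17 <- toy_recording(n_imu = 17L, strikes = c(1L, 10L))
  seg17 <- segment_motion(rec17)
  expect_equal(dim(seg17$blocks)[3], 3L)
  expect_equal(seg17$t_end, c(13L, 15L, 17L))
})

test_that("time-to-heel-strike labels are exact index arithmetic", {
  rec <- toy_recording(n_imu = 60L, strikes = c(11L, 31L, 51L))
  tti <- label_time_to_ic(rec)
  expect_equal(tti[11], 0)
  expect_equal(tti[21], 10 * 6.75) # 10 samples before the second strike
  # monotone decrease by one interval while approaching the next strike
  expect_equal(diff(tti[12:30]), rep(-6.75, 18))
  # samples after the last strike carry no label
  expect_true(all(is.na(tti[52:60])))
})

test_that("future-angle labels index the angle stream directly", {
  rec <- toy_recording(n_imu = 40L, angle = as.numeric(1:40))
  expect_equal(label_future_angle(rec, 0L), as.numeric(1:40))
  expect_equal(label_future_angle(rec, 15L)[1:25], as.numeric(16:40))
  expect_true(all(is.na(label_future_angle(rec, 15L)[26:40])))
  const <- toy_recording(n_imu = 40L, angle = rep(30, 40))
  for (h in c(1L, 5L, 10L, 15L)) {
    expect_equal(unique(stats::na.omit(label_future_angle(const, h))), 30)
  }
})

test_that("trimming drops both ends consistently", {
  rec <- generate_recording(gait_params(duration = 12, seed = 9))
  tr <- trim_recording(rec, 1, 1)
  expect_equal(tr$duration, 10)
  expect_equal(ncol(tr$semg), ncol(rec$semg) - 2 * round(rec$rates$semg))
  n_head <- round(rec$rates$imu)
  kept <- rec$heel_strikes[rec$heel_strikes > n_head &
                           rec$heel_strikes <= length(rec$angle) - n_head]
  expect_identical(tr$heel_strikes, as.integer(kept - n_head))
  expect_identical(trim_recording(rec, 0, 0)$semg, rec$semg)
  expect_error(trim_recording(rec, 7, 7), "shorter")
})

test_that("image and motion segmentations stay synchronized", {
  ds <- fix_dataset()
  rec <- fix_recording()
  end_img_ms <- (ds$t_end_semg - 1) * 1000 / rec$rates$semg
  end_mot_ms <- (ds$t_end_imu - 1) * 1000 / rec$rates$imu
  expect_true(all(abs(end_img_ms - end_mot_ms) <= 1000 / rec$rates$imu))
  # paired streams advance in lock-step
  expect_equal(diff(ds$t_end_semg), rep(15L, length(ds$t_end_semg) - 1L))
  expect_equal(diff(ds$t_end_imu), rep(2L, length(ds$t_end_imu) - 1L))
})

test_that("labeling is shift-equivariant", {
  rec <- toy_recording(n_imu = 80L, strikes = c(11L, 31L, 51L, 71L),
                       angle = sin(seq_len(80) / 5))
  k <- 4L
  shifted <- rec
  shifted$angle <- c(rep(0, k), rec$angle)[1:80]
  shifted$heel_strikes <- rec$heel_strikes + k
  shifted$heel_strikes <- shifted$heel_strikes[shifted$heel_strikes <= 80L]
  a <- label_time_to_ic(rec)
  b <- label_time_to_ic(shifted)
  n_cmp <- 80L - k - 10L
  expect_equal(b[(k + 1):(k + n_cmp)], a[1:n_cmp])
})
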