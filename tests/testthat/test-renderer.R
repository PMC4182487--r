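test_that("segment dwell follows step / velocity", {
  expect_equal(segment_dwell(100, 1), 0.010)
  expect_equal(segment_dwell(100, 5), 0.050)
  expect_equal(segment_dwell(25, 5), 0.200)
  expect_error(segment_dwell(0, 5), "velocity")
  expect_error(segment_dwell(50, -1), "step")
})

test_that("trajectory durations reproduce the printed design", {
  for (v in c(25, 50, 100)) {
    p <- motion_path(-70, 70, 5, v)
    expect_length(path_azimuths(p), 29)
    expect_equal(total_duration(p), 29 * 5 / v)
  }
  expect_equal(total_duration(motion_path(-70, 70, 5, 50)), 2.9)
  expect_equal(total_duration(motion_path(-70, 70, 5, 100)), 1.45)
  expect_equal(total_duration(motion_path(-70, 70, 5, 25)), 5.8)
  # one-position path lasts exactly one dwell
  expect_equal(total_duration(motion_path(10, 10, 5, 50)), 0.1)
  expect_error(motion_path(-70, 68, 5, 50), "multiple")
})

test_that("carrier construction is deterministic and correctly banded", {
  expect_length(carrier_band_centers(), 79)   # (16000 - 400)/200 + 1
  expect_equal(carrier_band_centers()[1], 400)
  expect_equal(tail(carrier_band_centers(), 1), 16000)
  c1 <- make_carrier(0.25, seed = 7)
  c2 <- make_carrier(0.25, seed = 7)
  expect_identical(c1, c2)
  expect_false(identical(c1, make_carrier(0.25, seed = 8)))
  expect_equal(sqrt(mean(c1^2)), 0.1, tolerance = 1e-12)
  # 20 Hz modulation: envelope autocorrelation peaks at the 50 ms lag
  fs <- 48000
  x2 <- make_carrier(1, seed = 7)^2
  ac <- stats::acf(x2, lag.max = round(0.06 * fs), plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  search <- round(0.03 * fs):round(0.06 * fs)
  peak_lag <- search[which.max(ac[search + 1])]
  expect_equal(peak_lag / fs, 0.050, tolerance = 0.02)
  # spectral energy confined to the filter bank's span
  spec <- Mod(fft(make_carrier(0.5, seed = 3)))^2
  f <- (0:(length(spec) - 1)) / length(spec) * fs
  in_band <- f >= 250 & f <= 16200
  out_band <- (f > 17000 & f <= fs / 2) | (f > 10 & f < 200)
  expect_lt(sum(spec[out_band]) / sum(spec[in_band]), 1e-4)
})

test_that("auditory paths are displaced behind or ahead of the visual path", {
  v_right <- motion_path(-70, 70, 5, 50)
  # positive offset = auditory lag: trails a rightward motion
  expect_equal(plan_trajectory(v_right, 10)$start_az, -80)
  expect_equal(plan_trajectory(v_right, 10)$end_az, 60)
  expect_equal(plan_trajectory(v_right, -10)$start_az, -60)
  # zero offset leaves the path unchanged
  expect_equal(plan_trajectory(v_right, 0)[c("start_az", "end_az")],
               v_right[c("start_az", "end_az")])
  # mirror symmetry: planning commutes with left/right reflection
  v_left <- motion_path(70, -70, 5, 50)
  for (mu in c(-10, -5, 0, 2.5, 10, 20)) {
    a_r <- plan_trajectory(v_right, mu)
    a_l <- plan_trajectory(v_left, mu)
    expect_equal(a_l$start_az, -a_r$start_az)
    expect_equal(a_l$end_az, -a_r$end_az)
    expect_equal(a_l$velocity, a_r$velocity)
  }
  expect_error(plan_trajectory(v_right, 25), "-90")
})

test_that("overlap-add rendering is exact for constant and identity filters", {
  fs <- 48000
  # constant random filter at every azimuth: segmented rendering must equal
  # one full convolution of the whole carrier
  h <- withr::with_seed(11, rnorm(257) * exp(-(0:256) / 80))
  azs <- seq(-90, 90, by = 5)
  const_set <- structure(
    list(azimuths = azs, step = 5, fs = fs, condition = "anechoic",
         left = matrix(h, nrow = length(h), ncol = length(azs)),
         right = matrix(h / 2, nrow = length(h), ncol = length(azs))),
    class = "spatial_filter_set"
  )
  path <- motion_path(-70, 70, 5, 100)
  carrier <- make_carrier(total_duration(path), fs, seed = 4)
  st <- render_motion(carrier, path, const_set)
  ref_l <- conv_full(carrier, h)
  rel_err <- max(abs(st$wave[, 1] - ref_l)) / max(abs(ref_l))
  expect_lt(rel_err, 1e-10)
  expect_equal(st$wave[, 2], conv_full(carrier, h / 2), tolerance = 1e-10,
               ignore_attr = TRUE)
  # energy is unchanged by segmentation
  expect_equal(sqrt(mean(st$wave[, 1]^2)), sqrt(mean(ref_l^2)),
               tolerance = 1e-12)
  # unit-impulse filters reproduce the carrier on both channels
  delta_set <- const_set
  delta_set$left <- matrix(c(1, numeric(16)), nrow = 17, ncol = length(azs))
  delta_set$right <- delta_set$left
  st2 <- render_motion(carrier, path, delta_set)
  n <- round(total_duration(path) * fs)
  expect_equal(st2$wave[seq_len(n), 1], carrier[seq_len(n)],
               tolerance = 1e-14, ignore_attr = TRUE)
  expect_equal(st2$wave[, 1], st2$wave[, 2], ignore_attr = TRUE)
})

test_that("single-position rendering equals brute-force convolution", {
  fs <- 48000
  set <- build_filter_set("anechoic", step = 5, hrir_length = 96)
  path <- motion_path(35, 35, 5, 100)   # one dwell at +35 degrees
  carrier <- make_carrier(total_duration(path), fs, seed = 2)
  st <- render_motion(carrier, path, set)
  pair <- filter_pair(set, 35)
  expect_equal(st$wave[, 1], oracle_conv(carrier, pair$left),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(st$wave[, 2], oracle_conv(carrier, pair$right),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("segment timing drift never exceeds one sample", {
  fs <- 48000
  # velocity chosen so dwell * fs is non-integer (48000/7 samples)
  path <- motion_path(-70, 70, 1, 7)
  azs <- seq(-90, 90, by = 1)
  set <- structure(
    list(azimuths = azs, step = 1, fs = fs, condition = "anechoic",
         left = matrix(c(1, 0), nrow = 2, ncol = length(azs)),
         right = matrix(c(1, 0), nrow = 2, ncol = length(azs))),
    class = "spatial_filter_set"
  )
  carrier <- sin(2 * pi * 5 * (0:(21 * fs)) / fs)[seq_len(ceiling(
    total_duration(path) * fs))]
  st <- render_motion(carrier, path, set)
  b <- st$segment_boundaries
  expect_equal(nrow(b), 141)
  dwell <- segment_dwell(7, 1)
  drift <- abs(b$end_sample - fs * dwell * seq_len(nrow(b)))
  expect_lt(max(drift), 1)
  expect_equal(b$start_sample[-1], b$end_sample[-nrow(b)] + 1)
})

test_that("rendering validates its inputs", {
  set <- build_filter_set("anechoic", step = 5, hrir_length = 64)
  path <- motion_path(-70, 70, 5, 50)
  expect_error(render_motion(numeric(10), path, set), "carrier too short")
  path1 <- motion_path(-70, 70, 1, 50)
  carrier <- make_carrier(0.2, seed = 1)
  expect_error(render_motion(carrier, path1, set), "step")
  # a path azimuth missing from the grid is named in the error
  off_path <- motion_path(-72, 68, 5, 100)
  carrier2 <- make_carrier(total_duration(off_path), seed = 1)
  expect_error(render_motion(carrier2, off_path, set), "-72")
})
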