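test_that("Woodworth ITD matches the closed form and its symmetries", {
  # independent evaluation of (a/c)(theta + sin theta) at 90 degrees
  expect_equal(woodworth_itd(90, 0.0875, 343),
               (0.0875 / 343) * (pi / 2 + 1), tolerance = 1e-12)
  expect_equal(woodworth_itd(90) * 1e6, 655.8, tolerance = 1e-3)
  expect_equal(woodworth_itd(0), 0)
  th <- seq(0, 90, by = 1)
  expect_equal(woodworth_itd(-th), -woodworth_itd(th))
  expect_true(all(diff(woodworth_itd(th)) > 0))  # strictly increasing
  expect_error(woodworth_itd(95), "azimuth")
})

test_that("synthesised HRIR pairs carry the expected binaural cues", {
  h0 <- synth_hrir(0)
  expect_identical(h0$left, h0$right)            # midline symmetry
  expect_true(all(is.finite(h0$left)))
  # cross-correlation lag between ears matches the Woodworth ITD
  for (az in c(30, 60, 90)) {
    h <- synth_hrir(az)
    cc <- stats::ccf(h$left, h$right, lag.max = 60, plot = FALSE)
    lag <- cc$lag[which.max(cc$acf)]
    expect_lte(abs(abs(lag) - woodworth_itd(az) * h$fs), 1)
    # head shadow: near (right) ear carries more high-frequency energy
    hp <- function(x) sum(diff(x)^2)
    expect_gt(hp(h$right), hp(h$left))
  }
  expect_error(synth_hrir(120), "azimuth")
})

test_that("Sabine absorption reproduces hand arithmetic and scaling", {
  room <- room_spec()  # 3.4 x 2.5 x 2.0 m, RT60 0.2 s
  s_total <- 2 * (3.4 * 2.5 + 3.4 * 2.0 + 2.5 * 2.0)
  expect_equal(s_total, 40.6)
  expect_equal(room$wall_absorption, 0.161 * 17 / (40.6 * 0.2),
               tolerance = 1e-12)
  expect_equal(prod(room$dimensions), 17, tolerance = 1e-9)
  # doubling RT60 halves alpha; alpha -> 0 as RT60 grows
  r2 <- room_spec(target_rt60 = 0.4)
  expect_equal(r2$wall_absorption, room$wall_absorption / 2)
  expect_lt(room_spec(target_rt60 = 100)$wall_absorption, 1e-3)
  # infeasible: tiny RT60 in a large room
  expect_error(room_spec(target_rt60 = 0.01), "infeasible")
  expect_error(room_spec(listener_position = c(5, 1, 1)), "inside")
})

test_that("image-source enumeration matches shoebox geometry", {
  room <- room_spec()
  im <- image_sources(room, 0, max_order = 1)
  expect_equal(sum(im$order == 0), 1)
  expect_equal(sum(im$order == 1), 6)     # one image per wall
  expect_equal(im$distance[im$order == 0], 1, tolerance = 1e-12)
  # nearest image for the default geometry is the ceiling (0.8 m above the
  # ears): path sqrt(1^2 + 1.6^2), computed by hand
  gap <- min(im$delay[im$order == 1]) - im$delay[im$order == 0]
  expect_equal(gap, (sqrt(1 + 1.6^2) - 1) / 343, tolerance = 1e-12)
  expect_true(gap * 1000 > 2.0 && gap * 1000 < 3.0)
  # sources at the arc extremes stay inside the room
  expect_silent(image_sources(room, 90, 1))
  expect_silent(image_sources(room, -90, 1))
})

test_that("fully absorbing walls leave only the direct path", {
  room <- room_spec(wall_absorption = 1)
  az <- 25
  b <- image_source_brir(room, az, max_order = 3, hrir_length = 128)
  h <- synth_hrir(az, length = 128L)
  shift <- round(1 / 343 * 48000)   # 1 m direct path
  expect_equal(b$left[shift + seq_len(128)], h$left, tolerance = 1e-12)
  expect_equal(b$right[shift + seq_len(128)], h$right, tolerance = 1e-12)
  expect_equal(sum(b$left[seq_len(shift)]^2), 0)
  expect_equal(sum(b$left[-seq_len(shift + 128)]^2), 0)
})

test_that("sweep round trip recovers known filters within the band", {
  fs <- 48000
  e <- ess_generate(300, 16000, 1, fs)     # the 1 s measurement sweep
  expect_equal(length(e$sweep), 48000)     # duration x fs
  # sweep * inverse concentrates at zero lag
  p <- conv_full(e$sweep, e$inverse)
  pk <- which.max(abs(p))
  expect_equal(pk, e$lag0)
  outside <- abs(seq_along(p) - pk) > 0.001 * fs
  expect_lt(sum(p[outside]^2) / sum(p^2), 0.01)
  # pure delay: peak moves to lag k
  k <- 13
  d <- ess_deconvolve(c(numeric(k), e$sweep), e, 50)
  expect_equal(which.max(abs(d)), k + 1)
  # random FIR filters no longer than 21 ms come back with small in-band
  # error (extraction window wide enough for the band-limiting ringing)
  for (seed in 1:3) {
    h <- withr::with_seed(seed, rnorm(1000) * exp(-(0:999) / 300))
    h <- h / sqrt(sum(h^2))
    rec <- conv_full(e$sweep, h)
    hr <- ess_deconvolve(rec, e, 1000 + 6000, pre = 1024)
    err <- inband_error(hr, c(numeric(1024), h), fs, 300, 16000)
    expect_lt(err, 1e-3)
  }
  expect_error(ess_generate(1000, 500, 1), "f1")
  expect_error(ess_generate(300, 30000, 1), "f1")
})

test_that("sweep instantaneous frequency runs from f1 to f2", {
  fs <- 48000
  e <- ess_generate(300, 16000, 1, fs, fade = 0)
  # phase-derivative estimate via the analytic signal, checked a little
  # inside each end to avoid edge effects of the discrete Hilbert transform
  n <- length(e$sweep)
  spec <- fft(e$sweep)
  spec[2:(n / 2)] <- 2 * spec[2:(n / 2)]
  spec[(n / 2 + 2):n] <- 0
  analytic <- fft(spec, inverse = TRUE) / n
  phase <- signal::unwrap(Arg(analytic))
  inst <- diff(phase) * fs / (2 * pi)
  t_probe <- c(0.005, 0.995)
  expected <- 300 * exp(t_probe * log(16000 / 300))
  measured <- inst[round(t_probe * fs)]
  expect_equal(measured, expected, tolerance = 0.01)
})

test_that("truncation preserves the 21 ms window after onset", {
  fs <- 48000
  # delta at the first sample: onset = 1, preserved length 1008
  ir <- c(1, numeric(3000))
  out <- truncate_brir(ir, keep = 0.021, fs = fs)
  expect_length(out, round(0.021 * fs))   # 1008 samples
  # delayed onset shifts the cut accordingly
  ir2 <- c(numeric(100), 1, numeric(3000))
  expect_length(truncate_brir(ir2, fs = fs), 101 + 1008 - 1)
  # short responses come back unchanged
  short <- c(1, numeric(100))
  expect_identical(truncate_brir(short, fs = fs), short)
  # truncation never adds energy
  long <- decay_ir(0.2, fs, dur = 0.1, seed = 5)
  expect_lte(sum(truncate_brir(long, fs = fs)^2), sum(long^2))
  expect_error(truncate_brir(ir, keep = 0, fs = fs), "keep")
})

test_that("filter sets satisfy their grid and symmetry invariants", {
  set1 <- build_filter_set("anechoic", step = 1, hrir_length = 128)
  expect_length(set1$azimuths, 181)
  set5 <- build_filter_set("anechoic", step = 5, hrir_length = 128)
  expect_length(set5$azimuths, 37)
  expect_equal(range(set5$azimuths), c(-90, 90))
  expect_true(all(diff(set5$azimuths) == 5))
  # midline interaural level difference < 0.5 dB broadband (exactly 0 here)
  p0 <- filter_pair(set5, 0)
  ild <- 10 * log10(sum(p0$left^2) / sum(p0$right^2))
  expect_lt(abs(ild), 0.5)
  # onset difference at 0 degrees below one sample
  expect_lt(abs(which.max(abs(p0$left)) - which.max(abs(p0$right))), 1)
  expect_error(filter_pair(set5, 2), "not in the filter set")
  expect_error(build_filter_set("reverberant"), "room_spec")
})

test_that("reverberant filter sets carry reflections inside 21 ms", {
  room <- room_spec()
  set <- build_filter_set("reverberant", room = room, step = 15)
  expect_equal(set$condition, "reverberant")
  for (az in set$azimuths) {
    pair <- filter_pair(set, az)
    refl <- detect_reflections(pair)
    expect_gte(length(refl), 2)
    expect_true(all(refl < 0.021))
  }
})

test_that("the sweep measurement round trip leaves filters nearly unchanged", {
  room <- room_spec()
  direct <- build_filter_set("reverberant", room = room, step = 45)
  measured <- build_filter_set("reverberant", room = room, step = 45,
                               ess_roundtrip = TRUE, ess_duration = 0.5)
  expect_equal(measured$azimuths, direct$azimuths)
  for (i in seq_along(direct$azimuths)) {
    n <- min(nrow(direct$left), nrow(measured$left))
    # the measurement is band-limited to the sweep band; compare there
    err <- inband_error(measured$left[1:n, i], direct$left[1:n, i],
                        48000, 400, 15000)
    expect_lt(err, 0.05)
  }
})

test_that("WAV round trip preserves filter sets", {
  dir <- withr::local_tempdir()
  set <- build_filter_set("anechoic", step = 45, hrir_length = 64)
  write_filter_set(set, dir)
  expect_setequal(list.files(dir),
                  sprintf("az%+04d.wav", seq(-90, 90, by = 45)))
  back <- read_filter_set(dir)
  expect_equal(back$azimuths, set$azimuths)
  expect_equal(back$fs, set$fs)
  expect_equal(back$left, set$left, tolerance = 1e-7, ignore_attr = TRUE)
  expect_equal(back$right, set$right, tolerance = 1e-7, ignore_attr = TRUE)
  # generic mono round trip
  x <- sin(2 * pi * 440 * (0:999) / 48000)
  f <- file.path(dir, "tone.wav")
  write_wav(x, 48000, f)
  w <- read_wav(f)
  expect_equal(w$fs, 48000)
  expect_equal(as.numeric(w$wave[, 1]), x, tolerance = 1e-7)
})
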