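test_that("ECG band-pass rejects DC and matches its frequency-response oracle", {
  fs <- 400
  zero <- bandpass_ecg(signal_record(rep(0, 10 * fs), fs))
  expect_true(all(zero$samples == 0))

  const <- bandpass_ecg(signal_record(rep(1, 30 * fs), fs))
  late <- const$samples[(10 * fs):(20 * fs)]
  expect_lt(max(abs(late)), 1e-3)

  tt <- (0:(30 * fs - 1)) / fs
  tone <- bandpass_ecg(signal_record(sin(2 * pi * 10 * tt), fs))
  mid <- tone$samples[(10 * fs):(20 * fs)]
  amp <- (max(mid) - min(mid)) / 2
  # zero-phase gain = |H|^2 of the underlying design
  gain <- sqrt(ansindex:::butter_bandpass_zp_gain(fs, 0.05, 40, 10))
  expect_lt(abs(amp - gain) / gain, 0.02)

  expect_error(bandpass_ecg(signal_record(rnorm(1000), fs = 60)),
               "too low")
})

test_that("R peaks of a clean 60 bpm record land on ground truth", {
  g <- generate_ecg(60, 0, 0, duration_s = 60, fs = 400, seed = 3,
                    jitter_ms = 0, snr_db = 20)
  beats <- detect_r_peaks(bandpass_ecg(g$record))
  expect_length(beats$beat_times_s, length(g$truth$beat_times_s))
  perf <- match_beats(beats$beat_times_s, g$truth$beat_times_s)
  expect_equal(perf$sensitivity, 1)
  expect_equal(perf$ppv, 1)
  expect_lt(perf$max_err_s, 0.010)
})

test_that("a flat record yields an empty beat series", {
  flat <- signal_record(rep(0, 400 * 20), 400)
  beats <- detect_r_peaks(flat)
  expect_length(beats$beat_times_s, 0)
  expect_error(detect_r_peaks(signal_record(rnorm(400 * 5), 400)),
               "at least 10 s")
})

test_that("detected RR series tracks sinusoidal rate modulation", {
  g <- generate_ecg(70, 50, 20, duration_s = 240, fs = 400, seed = 5,
                    snr_db = 25)
  beats <- detect_r_peaks(bandpass_ecg(g$record))
  expect_length(beats$beat_times_s, length(g$truth$beat_times_s))
  expect_gt(stats::cor(beats$rr_ms, g$truth$rr_ms), 0.99)
})

test_that("RR cleaning flags implanted artifacts and only those", {
  t_reg <- cumsum(c(0, rep(1, 29)))           # 30 beats at 1000 ms
  clean <- clean_rr(beat_series(t_reg))
  expect_false(any(clean$corrected_flags))
  expect_equal(clean$rr_ms, rep(1000, 29))

  t_bad <- t_reg
  t_bad[16] <- t_bad[15] + 0.4                # one 400 ms interval
  bad <- beat_series(t_bad)
  cleaned <- clean_rr(bad)
  expect_identical(sum(cleaned$corrected_flags), 2L)  # 400 ms + 1600 ms pair
  expect_true(all(abs(cleaned$rr_ms - 1000) < 150))

  t_mess <- cumsum(c(0, rep(c(1, 1, 0.4), 10)))       # 30% short intervals
  expect_error(clean_rr(beat_series(t_mess)), "rejected")
  expect_error(clean_rr(beat_series(c(0, 1, 2))), "at least 6")
})

test_that("RR resampling is exact for constants and cubic polynomials", {
  tt <- cumsum(c(0, rep(0.8, 301)))
  rr4 <- resample_rr(beat_series(tt), 4)
  expect_equal(rr4$fs, 4)
  expect_true(all(abs(rr4$samples - 800) < 1e-9))

  # 240 s span at 4 Hz -> 960 samples
  t240 <- cumsum(c(0, rep(1, 240)))
  expect_length(resample_rr(beat_series(t240), 4)$samples, 960)

  # RR following a cubic polynomial of time: beat times are solved so
  # that each interval equals the polynomial at its terminating beat,
  # making (beat time, RR) nodes lie exactly on the cubic; the spline
  # must then reproduce the polynomial itself
  poly <- function(t) 800 + 2 * t - 0.05 * t^2 + 3e-4 * t^3
  tb <- 0
  while (tb[length(tb)] < 60) {
    tn <- tb[length(tb)]
    tn1 <- tn + poly(tn) / 1000
    for (it in 1:50) tn1 <- tn + poly(tn1) / 1000
    tb <- c(tb, tn1)
  }
  out <- resample_rr(beat_series(tb), 4)
  grid <- out$t0 + (seq_along(out$samples) - 1) / 4
  expect_lt(max(abs(out$samples - poly(grid))) / 800, 1e-6)
  expect_error(resample_rr(beat_series(c(0, 1, 2, 3)), 4), "at least 4")
})

test_that("HRV indices separate LF and HF tones", {
  t4 <- (0:959) / 4
  lf <- hrv_indices(signal_record(1000 + 50 * sin(2 * pi * 0.1 * t4), 4,
                                  units = "ms"))
  expect_gte(lf$HRVLFn, 0.9)
  expect_lte(lf$HRVHFn, 0.05)
  hf <- hrv_indices(signal_record(1000 + 50 * sin(2 * pi * 0.3 * t4), 4,
                                  units = "ms"))
  expect_gte(hf$HRVHFn, 0.9)
  expect_error(
    hrv_indices(signal_record(rep(800, 960), 4, units = "ms")),
    "zero total"
  )
})

test_that("normalized HRV indices are scale-free and bounded", {
  set.seed(11)
  t4 <- (0:959) / 4
  x <- 1000 + 30 * sin(2 * pi * 0.11 * t4) + 20 * sin(2 * pi * 0.27 * t4) +
    rnorm(960, 0, 5)
  h1 <- hrv_indices(signal_record(x, 4, units = "ms"))
  h3 <- hrv_indices(signal_record(1000 + 3 * (x - 1000), 4, units = "ms"))
  expect_equal(h3$HRVLF, 9 * h1$HRVLF, tolerance = 1e-9)
  expect_equal(h3$HRVHF, 9 * h1$HRVHF, tolerance = 1e-9)
  expect_equal(h3$HRVLFn, h1$HRVLFn, tolerance = 1e-9)
  expect_equal(h3$HRVHFn, h1$HRVHFn, tolerance = 1e-9)
  expect_lte(h1$HRVLFn + h1$HRVHFn, 1)
})

test_that("the full ECG-to-HRV pipeline recovers a pure LF mix", {
  g <- generate_ecg(65, 50, 0, duration_s = 240, fs = 400, seed = 21,
                    jitter_ms = 1, snr_db = 25)
  h <- ecg_to_hrv(g$record)
  expect_gte(h$HRVLFn, 0.9)
})
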