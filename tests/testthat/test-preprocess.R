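fs <- 300

test_that("the band-pass design meets its frequency-response contract", {
  spec <- design_fir_bandpass(2, 30, 496, fs)
  expect_length(spec$coefficients, 497L)
  # linear phase: symmetric taps, group delay order/2 samples
  expect_equal(spec$coefficients, rev(spec$coefficients), tolerance = 1e-12)
  h <- aepdecode:::fir_response(spec, c(0.5, 10, 60))
  expect_lt(abs(20 * log10(h[2])), 1)        # < 1 dB ripple at 10 Hz
  expect_lt(20 * log10(h[1]), -20)           # >= 20 dB down at 0.5 Hz
  expect_lt(20 * log10(h[3]), -20)           # >= 20 dB down at 60 Hz
  expect_error(design_fir_bandpass(order = 497), "even")
  expect_error(design_fir_bandpass(2, 200, 496, fs), "band edges")
})

test_that("zero-phase filtering passes the band and rejects stop-band tones", {
  spec <- design_fir_bandpass(2, 30, 496, fs)
  t <- (0:(20 * fs - 1)) / fs
  mid <- (5 * fs):(15 * fs)
  x10 <- sin(2 * pi * 10 * t)
  y10 <- apply_filter(spec, x10)
  expect_equal(sine_amplitude(y10[mid], 10, fs), 1, tolerance = 0.05)
  # zero net phase: filtered 10 Hz stays in phase with the input
  expect_gt(stats::cor(y10[mid], x10[mid]), 0.9999)

  mix <- sin(2 * pi * 10 * t) + sin(2 * pi * 60 * t)
  ymix <- apply_filter(spec, mix)
  expect_lt(sine_amplitude(ymix[mid], 60, fs), 10^(-20 / 20))

  # DC is outside the pass band
  expect_lt(max(abs(apply_filter(spec, rep(1, length(t)))[mid])), 1e-3)

  # filtering twice equals the squared magnitude response (spectral oracle)
  x25 <- sin(2 * pi * 2.5 * t)
  g1 <- sine_amplitude(apply_filter(spec, x25)[mid], 2.5, fs)
  g2 <- sine_amplitude(apply_filter(spec, apply_filter(spec, x25))[mid], 2.5, fs)
  expect_equal(g2, g1^2, tolerance = 1e-3)

  expect_error(apply_filter(spec, rnorm(1000)), "too short")
})

test_that("filtering commutes with channel selection", {
  spec <- design_fir_bandpass(2, 30, 496, fs)
  X <- matrix(rnorm(6 * 5000), 6)
  keep <- c(1, 3, 5)
  expect_equal(apply_filter(spec, X)[keep, ],
               apply_filter(spec, X[keep, ]))
})

test_that("each bad-channel rule fires on its planted defect and not on clean data", {
  sim <- simulate_recording(session_config(
    n_channels = 16, n_chirp = 40, seed = 301,
    planted_bad_channels = list(list(channel = 2, kind = "flatline"),
                                list(channel = 9, kind = "high_amplitude"),
                                list(channel = 14, kind = "decorrelated"))))
  flagged <- detect_bad_channels(sim$recording)
  expect_setequal(flagged, c("ch02", "ch09", "ch14"))
  reasons <- attr(flagged, "reasons")
  expect_true("ch02" %in% reasons$flatline)
  expect_true("ch09" %in% reasons$amplitude)
  expect_true("ch14" %in% reasons$correlation)

  clean <- quiet_session()
  expect_length(detect_bad_channels(clean$recording), 0L)
})

test_that("the bad-channel report serialises reasons to JSON", {
  sim <- simulate_recording(session_config(
    n_channels = 8, n_chirp = 10, seed = 71,
    planted_bad_channels = list(list(channel = 3, kind = "flatline"))))
  flagged <- detect_bad_channels(sim$recording)
  path <- withr::local_tempfile(fileext = ".json")
  write_bad_channel_report(flagged, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_true("ch03" %in% back$removed)
  expect_true("ch03" %in% back$reasons$flatline)
})

test_that("a single 150 uV excursion triggers the amplitude rule", {
  sim <- quiet_session()
  rec <- sim$recording
  rec$data[5, 1000:1050] <- rec$data[5, 1000:1050] + 150
  expect_true("ch05" %in% detect_bad_channels(rec))
})

test_that("a line-noisy channel triggers the line-noise z rule", {
  # a lone outlier among n channels has z at most (n-1)/sqrt(n), so the
  # 4 SD rule needs a realistically large montage to be able to fire
  set.seed(8)
  X <- matrix(rnorm(40 * 40 * fs), 40)
  t <- (0:(40 * fs - 1)) / fs
  X[11, ] <- X[11, ] + 8 * sin(2 * pi * 60 * t)
  rec <- eeg_recording(X, fs)
  flagged <- detect_bad_channels(rec)
  expect_true("ch11" %in% attr(flagged, "reasons")$line_noise)
})

test_that("calibration mask keeps clean data and rejects planted bursts", {
  set.seed(4)
  n <- 240 * fs
  X <- matrix(rnorm(8 * n), 8)
  rec <- eeg_recording(X, fs)
  expect_gte(mean(select_calibration_mask(rec)), 0.99)

  burst_at <- seq(10, 110, by = 12) * fs      # ~10% of windows
  Xb <- X
  for (b in burst_at) Xb[, b:(b + fs - 1)] <- Xb[, b:(b + fs - 1)] + 40
  recb <- eeg_recording(Xb, fs)
  mask <- select_calibration_mask(recb)
  for (b in burst_at) expect_false(any(mask[b:(b + fs - 1)]))
  expect_identical(mask, select_calibration_mask(recb))  # deterministic

  # mostly-artifactual short recording: not enough clean seconds survive
  Xs <- matrix(rnorm(8 * 35 * fs), 8)
  Xs[, 1:(20 * fs)] <- Xs[, 1:(20 * fs)] * 50
  expect_error(select_calibration_mask(eeg_recording(Xs, fs)),
               "clean calibration")
})

test_that("ASR statistics are identity-like on white noise and homogeneous", {
  set.seed(12)
  X <- matrix(rnorm(8 * 60 * fs), 8)
  m1 <- asr_fit(X, fs = fs)
  expect_lt(norm(m1$mixing_sqrt - diag(8), "F"), 0.05)
  m2 <- asr_fit(2 * X, fs = fs)
  expect_equal(m2$thresholds, 2 * m1$thresholds, tolerance = 1e-9)
  expect_equal(asr_fit(X, fs = fs)$thresholds, m1$thresholds)  # reproducible
  Xdeg <- X; Xdeg[3, ] <- 0
  expect_error(asr_fit(Xdeg, fs = fs), "ch03")
  expect_error(asr_fit(X[, 1:(10 * fs)], fs = fs), ">= 30 s")
})

test_that("ASR removes planted bursts, spares clean data, and is stable", {
  set.seed(13)
  calib <- matrix(rnorm(8 * 60 * fs), 8)
  model <- asr_fit(calib, fs = fs)

  Y <- matrix(rnorm(8 * 20 * fs), 8)
  expect_lt(rms(asr_process(model, Y) - Y) / rms(Y), 0.01)

  bidx <- (10 * fs):(10.5 * fs)
  Yb <- Y
  Yb[1:3, bidx] <- Yb[1:3, bidx] + 500 * sin(2 * pi * 5 * seq_along(bidx) / fs)
  Yc <- asr_process(model, Yb)
  expect_gt(1 - rms(Yc[1:3, bidx]) / rms(Yb[1:3, bidx]), 0.80)
  out <- setdiff(seq_len(ncol(Y)), bidx)
  expect_lt(rms(Yc[, out] - Yb[, out]) / rms(Yb[, out]), 0.10)

  # processing already-cleaned data is a near no-op
  expect_lt(rms(asr_process(model, Yc) - Yc) / rms(Yc), 0.02)
})
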