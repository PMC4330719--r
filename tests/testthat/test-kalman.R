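fs <- 300

test_that("the state-space impulse responses peak at 100 and 300 ms with unit gain", {
  m <- build_erp_model(fs)
  ir <- erp_impulse_response(m, 0.5)
  expect_equal((which.max(abs(ir$early)) - 1) / fs * 1000, 100)
  expect_equal((which.max(ir$late) - 1) / fs * 1000, 300)
  expect_equal(min(ir$early), -1, tolerance = 1e-9)   # N100 negativity
  expect_equal(max(ir$late), 1, tolerance = 1e-9)
  expect_lt(max(abs(eigen(m$A)$values)), 1)            # stable
  expect_equal(m$R / m$q, 0.001)
  expect_error(build_erp_model(20), "fewer than 3 samples")
  expect_error(build_erp_model(fs, 0.3, 0.1), "peak_early_s < peak_late_s")
})

test_that("the filter covariance converges to the Riccati fixed point", {
  m <- build_erp_model(fs)
  est <- kalman_filter_erp(m, rnorm(2000), c(100L, 700L))
  P_ss <- riccati_fixed_point(m)
  expect_lt(norm(est$final_covariance - P_ss, "F") / norm(P_ss, "F"), 1e-8)
  # P symmetric PSD
  expect_equal(est$final_covariance, t(est$final_covariance))
  expect_true(all(eigen(est$final_covariance, symmetric = TRUE)$values > 0))
})

test_that("limits: vanishing measurement noise tracks, dominant noise suppresses", {
  t <- seq_len(3000) / fs
  y <- sin(2 * pi * 3 * t) + 0.3 * sin(2 * pi * 11 * t)
  m0 <- build_erp_model(fs, ratio = 1e-12)
  e0 <- kalman_filter_erp(m0, y, integer(0))
  after <- (fs + 1):3000
  expect_lt(rms(e0$estimate[after] - y[after]) / rms(y[after]), 0.01)

  # prior-dominated: measurement noise huge relative to state noise
  m1 <- build_erp_model(fs, ratio = 1e15, q = 1)
  e1 <- kalman_filter_erp(m1, y, integer(0))
  expect_lt(max(abs(e1$estimate)), 1e-6 * rms(y))
})

test_that("matched-model filtering denoises an ERP train at 0 dB SNR", {
  m <- build_erp_model(fs)
  n <- 10 * fs
  onsets <- seq(150L, n - 200L, by = 450L)
  ir <- erp_impulse_response(m, 0.45)
  truth <- numeric(n)
  for (o in onsets) {
    idx <- (o + 1):(o + length(ir$combined))
    truth[idx] <- truth[idx] + ir$combined
  }
  wins <- 0
  for (sd in 1:100) {
    set.seed(sd)
    y <- truth + rnorm(n, sd = rms(truth))
    est <- kalman_filter_erp(m, y, onsets)$estimate
    if (rms(est - truth) < rms(y - truth)) wins <- wins + 1
  }
  expect_gte(wins, 95)
})

test_that("the filter is causal and linear", {
  m <- build_erp_model(fs)
  set.seed(1)
  y <- rnorm(1200)
  onsets <- c(50L, 600L)
  e1 <- kalman_filter_erp(m, y, onsets)$estimate
  y2 <- y
  y2[801:1200] <- y2[801:1200] + 10
  e2 <- kalman_filter_erp(m, y2, onsets)$estimate
  expect_equal(e1[1:800], e2[1:800])

  e3 <- kalman_filter_erp(m, 2.5 * y, onsets, onset_gain = 2.5)$estimate
  expect_equal(e3, 2.5 * e1, tolerance = 1e-10)
})

test_that("non-finite samples are rejected with a location", {
  m <- build_erp_model(fs)
  y <- rnorm(500)
  y[123] <- NaN
  expect_error(kalman_filter_erp(m, y, integer(0)), "123")
})

test_that("epoching returns 150-sample trials and respects bounds", {
  ev <- generate_events(10, seed = 3)
  n <- max(ev$onset_sample) + 150
  x <- rnorm(n)
  ep <- epoch_signal(x, ev)
  expect_equal(dim(ep), c(20L, 150L))
  expect_equal(attr(ep, "labels"), ev$label)
  expect_equal(ep[1, ], x[(ev$onset_sample[1] + 1):(ev$onset_sample[1] + 150)])

  expect_equal(nrow(epoch_signal(x, integer(0), fs = fs)), 0L)
  const <- epoch_signal(rep(3, n), ev)
  expect_true(all(const == 3))
  expect_error(epoch_signal(x[1:100], ev), "cross the signal bounds")
})
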