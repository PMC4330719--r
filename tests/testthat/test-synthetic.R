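test_that("stimulus schedules have the right counts, spacing, and no overlap", {
  ev <- generate_events(200, seed = 7)
  expect_equal(as.vector(table(ev$label)), c(200, 200))
  sil <- inter_chirp_silences(ev)
  expect_true(all(sil >= 0.6 - 1e-9 & sil <= 2.5 + 1e-9))

  # silent epochs overlap neither chirp epochs nor each other, across seeds
  for (sd in 1:5) {
    e <- generate_events(50, seed = sd)
    ep <- 150L
    ch <- e$onset_sample[e$label == "chirp"]
    si <- sort(e$onset_sample[e$label == "silent"])
    expect_true(all(diff(si) >= ep))
    for (o in si) expect_false(any(o < ch + ep & o + ep > ch))
  }

  # minimal schedule
  e1 <- generate_events(1, seed = 1)
  expect_equal(nrow(e1), 2L)

  # determinism
  expect_identical(generate_events(30, seed = 5), generate_events(30, seed = 5))
})

test_that("inter-chirp silences are uniform on the configured range", {
  ev <- generate_events(10001, seed = 11)
  sil <- inter_chirp_silences(ev)
  ks <- suppressWarnings(stats::ks.test(sil, "punif", 0.6, 2.5))
  expect_gt(ks$p.value, 0.01)
})

test_that("silent placement fails loudly when the silence budget is too small", {
  expect_error(generate_events(50, isi_min_s = 0.6, isi_max_s = 0.65, seed = 1),
               "deficit")
})

test_that("the canonical ERP template peaks at 100 and 300 ms", {
  w <- canonical_erp()
  expect_equal(length(w), 150L)
  early <- canonical_erp(amp_early = -1, amp_late = 0)
  expect_equal(which.min(early) - 1L, 30L)   # 100 ms at 300 Hz
  expect_equal(min(early), -1)
  late <- canonical_erp(amp_early = 0, amp_late = 1)
  expect_equal(which.max(late) - 1L, 90L)    # 300 ms
  expect_equal(max(late), 1)
  expect_equal(canonical_erp(amp_early = 0, amp_late = 0), rep(0, 150))
  expect_error(canonical_erp(tau_early_s = 0), "positive")
})

test_that("simulated recordings reconstruct exactly from mixing and sources", {
  sim <- quiet_session()
  expect_equal(max(abs(sim$recording$data -
                         sim$truth$mixing %*% sim$truth$sources)), 0)
})

test_that("fixed seeds give bit-identical recordings", {
  cf <- session_config(n_channels = 8, n_chirp = 10, seed = 99)
  s1 <- simulate_recording(cf)
  s2 <- simulate_recording(cf)
  expect_identical(s1$recording$data, s2$recording$data)
  expect_identical(s1$truth$sources, s2$truth$sources)
})

test_that("doubling erp_snr doubles the ERP contribution at every channel", {
  c1 <- session_config(n_channels = 8, n_chirp = 10, erp_snr = 0.4, seed = 3)
  c2 <- session_config(n_channels = 8, n_chirp = 10, erp_snr = 0.8, seed = 3)
  s1 <- simulate_recording(c1)
  s2 <- simulate_recording(c2)
  erp1 <- outer(s1$truth$mixing[, "erp"], s1$truth$sources["erp", ])
  erp2 <- outer(s2$truth$mixing[, "erp"], s2$truth$sources["erp", ])
  ratio <- apply(erp2, 1, function(r) sqrt(mean(r^2))) /
    apply(erp1, 1, function(r) sqrt(mean(r^2)))
  expect_equal(ratio, rep(2, 8), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("in the noise-free limit the chirp-locked average is the template", {
  sim <- simulate_recording(session_config(n_channels = 8, n_chirp = 30,
                                           erp_snr = 1e6, seed = 21,
                                           amp_jitter_sd = 0,
                                           lat_jitter_sd_s = 0))
  best <- sim$truth$best_channel
  ep <- epoch_signal(sim$recording$data[best, ], sim$recording$events)
  avg <- colMeans(ep[attr(ep, "labels") == "chirp", ])
  expect_gt(abs(stats::cor(avg, canonical_erp())), 0.999)
})

test_that("a planted flatline channel is constant for more than 5 seconds", {
  sim <- simulate_recording(session_config(
    n_channels = 8, n_chirp = 20, seed = 13,
    planted_bad_channels = list(list(channel = 4, kind = "flatline"))))
  x <- sim$recording$data[4, ]
  runs <- abs(diff(x)) < 1e-6
  expect_gt(sum(runs) + 1, 5 * sim$recording$fs)
})

test_that("event TSV round-trips through disk", {
  ev <- generate_events(20, seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_events_tsv(ev, path)
  back <- read_events_tsv(path, fs = 300)
  expect_equal(back$onset_sample, ev$onset_sample)
  expect_equal(as.character(back$label), as.character(ev$label))
})
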