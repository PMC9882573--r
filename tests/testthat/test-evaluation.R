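test_that("SNR improvement follows the power-ratio definition", {
  clean <- sin(seq(0, 20, length.out = 500))
  noisy <- clean + rnorm(500, sd = 0.3)

  expect_equal(snr_improvement(clean, noisy, noisy), 0)

  # halving the residual power gives 10 log10(2) dB
  den <- clean + (noisy - clean) / sqrt(2)
  expect_equal(snr_improvement(clean, noisy, den), 10 * log10(2),
               tolerance = 1e-9)

  # perfect recovery is capped by the epsilon floor, not infinite
  imp <- snr_improvement(clean, noisy, clean)
  expect_true(is.finite(imp))
  expect_equal(imp, 10 * log10(sum((noisy - clean)^2) /
                                 (1e-12 * sum(clean^2))))

  expect_error(snr_improvement(numeric(10), rnorm(10), rnorm(10)), "zero power")
  expect_error(snr_improvement(clean, noisy[-1], noisy[-1]), "equal length")
})

test_that("QT estimates match the generator's analytic landmarks", {
  sim <- study_sim()
  seg <- segment_beats(sim$truth$r_peak, n_samples(sim$record))
  qt <- estimate_qt(sim$record, seg)
  err <- qt$qt_s - sim$truth$true_qt
  expect_lt(max(abs(err), na.rm = TRUE), 0.020)
  expect_lt(mean(is.na(qt$qt_s)), 0.05)
})

test_that("beats without a T wave are skipped, identical beats agree", {
  flat_t <- wave_params(amplitude = c(P = 0.15, Q = -0.08, R = 1, S = -0.15, T = 0))
  sim <- generate_clean(synth_spec(waves = flat_t, mean_rr = 1, rr_jitter_sd = 0,
                                   amplitude_jitter_cv = 0, duration = 12, seed = 2))
  seg <- segment_beats(sim$truth$r_peak, n_samples(sim$record))
  qt <- estimate_qt(sim$record, seg)
  expect_true(all(is.na(qt$qt_s)))

  simr <- generate_clean(regular_spec(duration = 12))
  segr <- segment_beats(simr$truth$r_peak, n_samples(simr$record))
  qtr <- estimate_qt(simr$record, segr)
  interior <- qtr$qt_s[3:8]
  expect_lt(diff(range(interior)), 1e-9)
})

test_that("QT differences track constructed distortions", {
  base <- synth_spec(mean_rr = 0.8, rr_jitter_sd = 0, amplitude_jitter_cv = 0,
                     duration = 20, seed = 6)
  sim <- generate_clean(base)
  seg <- segment_beats(sim$truth$r_peak, n_samples(sim$record))

  # identical records: all differences zero
  dq0 <- delta_qt(sim$record, sim$record, seg)
  expect_true(all(dq0$delta_qt == 0, na.rm = TRUE))
  expect_equal(attr(dq0, "median"), 0)
  expect_equal(attr(dq0, "iqr"), 0)

  # shift the T wave late by exactly 8 ms: median difference ~ +8 ms
  wv <- wave_params()
  wv$center[wv$wave == "T"] <- wv$center[wv$wave == "T"] + 2 * pi * 0.008 / 0.8
  shifted <- generate_clean(synth_spec(waves = wv, mean_rr = 0.8,
                                       rr_jitter_sd = 0, amplitude_jitter_cv = 0,
                                       duration = 20, seed = 6))
  dq <- delta_qt(sim$record, shifted$record, seg)
  expect_lt(abs(attr(dq, "median") - 0.008), 0.003)
})

test_that("the benchmark grid is complete, tidy and deterministic", {
  sim <- generate_clean(synth_spec(duration = 20, seed = 3))
  b1 <- run_benchmark_grid(sim$record, levels = c(5, 15), reps = 2, seed0 = 9)
  expect_equal(nrow(b1$snr), 2 * 2 * 3)       # levels x reps x methods x leads
  expect_setequal(unique(b1$snr$method), c("prior", "posterior", "wavelet"))
  expect_true(all(b1$snr$status == "ok"))

  b2 <- run_benchmark_grid(sim$record, levels = c(5, 15), reps = 2, seed0 = 9)
  expect_identical(b1$snr, b2$snr)
  expect_identical(b1$qt, b2$qt)

  s <- summarise_snr(b1)
  expect_equal(nrow(s), 2 * 3)
  expect_true(all(c("mean_db", "sd_db") %in% names(s)))
  q <- summarise_qt(b1)
  expect_true(all(c("median_dqt_s", "iqr_dqt_s") %in% names(q)))
})
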