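test_that("generation is deterministic and beats land where constructed", {
  s <- regular_spec()
  a <- generate_clean(s)
  b <- generate_clean(s)
  expect_identical(a$record$samples, b$record$samples)
  expect_identical(a$truth, b$truth)

  # 1 s beats over 10 s at 250 Hz: exactly 10 R peaks, 250 samples apart
  expect_equal(nrow(a$truth), 10L)
  expect_equal(diff(a$truth$r_peak), rep(250L, 9))

  # R peaks coincide with the per-beat argmax of the clean signal
  x <- get_lead(a$record, 1)
  for (r in a$truth$r_peak) {
    w <- max(1, r - 30):min(length(x), r + 30)
    expect_equal(w[which.max(x[w])], r)
  }
  # landmark ordering within each beat
  expect_true(all(a$truth$q_onset < a$truth$r_peak))
  expect_true(all(a$truth$r_peak < a$truth$t_offset, na.rm = TRUE))
  expect_true(all(diff(a$truth$r_peak) > 0))
})

test_that("all-zero amplitudes give a silent record with intact beat count", {
  wp <- wave_params(amplitude = c(P = 0, Q = 0, R = 0, S = 0, T = 0))
  sim <- generate_clean(synth_spec(waves = wp, mean_rr = 1, rr_jitter_sd = 0,
                                   duration = 10, seed = 3))
  expect_true(all(sim$record$samples == 0))
  expect_equal(nrow(sim$truth), 10L)
})

test_that("spec invariants are enforced", {
  expect_error(wave_params(width = c(P = 0.2, Q = -0.1, R = 0.05, S = 0.03, T = 0.3)),
               "positive")
  expect_error(wave_params(center = c(P = 0.5, Q = -0.06, R = 0, S = 0.12, T = 1.8)),
               "increasing")
  expect_error(wave_params(amplitude = c(P = 0.1, Q = -2, R = 1, S = -0.1, T = 0.3)),
               "dominate")
  expect_error(synth_spec(mean_rr = 0.05, fs = 250), "at least 20")
  expect_error(synth_spec(rr_jitter_sd = 0.5, mean_rr = 1), "mean_rr / 3")
})

test_that("noise is power-matched to the requested SNR exactly", {
  rec <- generate_clean(regular_spec())$record
  # 0 dB: realized noise power equals signal power
  out <- add_noise(rec, 0, seed = 2)
  nz <- out$record$samples[, 1] - rec$samples[, 1]
  expect_equal(mean(nz^2), mean(rec$samples[, 1]^2), tolerance = 1e-12)

  # 10 dB: noise power is a tenth of signal power
  out <- add_noise(rec, 10, seed = 2)
  nz <- out$record$samples[, 1] - rec$samples[, 1]
  expect_equal(mean(nz^2), mean(rec$samples[, 1]^2) / 10, tolerance = 1e-12)
  expect_equal(unname(out$noise_var[1]), mean(nz^2), tolerance = 1e-12)

  # measured output SNR equals the request to far below 1e-9 dB
  for (snr in c(-5, 3.3, 17)) {
    out <- add_noise(rec, snr, seed = 5)
    nz <- out$record$samples[, 1] - rec$samples[, 1]
    got <- 10 * log10(mean(rec$samples[, 1]^2) / mean(nz^2))
    expect_equal(got, snr, tolerance = 1e-9)
  }

  # a very large SNR leaves the record essentially untouched
  out <- add_noise(rec, 300, seed = 2)
  expect_equal(out$record$samples, rec$samples, tolerance = 1e-12)

  expect_error(add_noise(ecg_record(rep(0, 100), fs = 100), 10), "zero power")
})

test_that("baseline wander is additive, scaled and reproducible", {
  rec <- generate_clean(regular_spec())$record
  expect_identical(add_baseline_wander(rec, amplitude = 0)$samples, rec$samples)

  zero <- ecg_record(rep(0, 2500), fs = 250)
  drift <- add_baseline_wander(zero, amplitude = 1, freq = 0.3, seed = 4)
  expect_gt(max(abs(drift$samples)), 0.5)
  expect_lt(max(abs(drift$samples)), 1.5)

  d2 <- add_baseline_wander(zero, amplitude = 1, freq = 0.3, seed = 4)
  expect_identical(drift$samples, d2$samples)
})

test_that("the warped-beat sample mean converges to the beat template", {
  rmse <- sapply(c(10, 40), function(nb) {
    sim <- generate_clean(synth_spec(mean_rr = 0.8, rr_jitter_sd = 0.03,
                                     amplitude_jitter_cv = 0,
                                     duration = nb * 0.8 + 1, seed = 9))
    noisy <- add_noise(sim$record, 10, seed = 9)$record
    seg <- segment_beats(sim$truth$r_peak, n_samples(noisy))
    ens <- build_ensemble(get_lead(noisy, 1), seg, n_phase = 300)
    ens_clean <- build_ensemble(get_lead(sim$record, 1), seg, n_phase = 300)
    mu <- colMeans(ens$beats)
    template <- colMeans(ens_clean$beats)
    sqrt(mean((mu - template)^2))
  })
  expect_lt(rmse[2], rmse[1])
})
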