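make_ens <- function(beats, n_phase = ncol(beats)) {
  # identical-length beats laid end to end with centred R peaks
  n <- ncol(beats)
  sig <- as.vector(t(beats))
  peaks <- (seq_len(nrow(beats)) - 1) * n + ceiling((n + 2) / 2)
  seg <- segment_beats(peaks, length(sig))
  build_ensemble(sig, seg, n_phase = n_phase)
}

test_that("ensembles stack warped beats with aligned R columns", {
  beat <- c(0, 0.1, 1, 0.2, 0)
  ens <- make_ens(matrix(rep(beat, 4), 4, byrow = TRUE), n_phase = 8)
  expect_equal(dim(ens$beats), c(4L, 8L))
  expect_true(all(apply(ens$beats, 2, function(cc) length(unique(cc))) == 1))

  # differing beat lengths, R column holds each beat's R value
  set.seed(2)
  sim <- generate_clean(synth_spec(duration = 30, seed = 2))
  seg <- segment_beats(sim$truth$r_peak, n_samples(sim$record))
  x <- get_lead(sim$record, 1)
  ens <- build_ensemble(x, seg, n_phase = 300)
  expect_equal(ncol(ens$beats), 300L)
  expect_equal(ens$beats[, ens$r_phase], x[seg$r_peak])

  expect_error(build_ensemble(x, seg, n_phase = max(seg$n_i) - 1L), "longer than")
  seg1 <- seg[1, ]
  attr(seg1, "n_total") <- attr(seg, "n_total")
  class(seg1) <- class(seg)
  expect_error(build_ensemble(x, seg1, n_phase = 300), "multiple beats")
})

test_that("sample statistics match hand-computed values and recover truth", {
  ens <- make_ens(matrix(c(0, 2, 2, 0), 2, byrow = TRUE))
  fit <- gp_fit(ens, mode = "full")
  expect_equal(fit$mu, c(1, 1))
  expect_equal(fit$k_full, matrix(c(1, -1, -1, 1), 2))  # 1/B normalization
  expect_equal(fit$k_diag, c(1, 1))

  const <- make_ens(matrix(5, 3, 4))
  fitc <- gp_fit(const)
  expect_equal(fitc$mu, rep(5, 4))
  expect_equal(fitc$k_diag, rep(0, 4))

  # Monte Carlo: i.i.d. rows from a known diagonal Gaussian
  set.seed(31)
  tt <- 12
  mu_star <- rnorm(tt)
  k_star <- runif(tt, 0.5, 2)
  b <- 2000
  rows <- sapply(seq_len(tt), function(j) rnorm(b, mu_star[j], sqrt(k_star[j])))
  ens <- structure(list(beats = rows, maps = NULL, n_phase = tt,
                        r_phase = NA_integer_, seg = NULL),
                   class = "phase_ensemble")
  fit <- gp_fit(ens)
  expect_lt(max(abs(fit$mu - mu_star)), 5 * sqrt(max(k_star) / b))
  expect_lt(max(abs(fit$k_diag - k_star)), 5 * max(k_star) * sqrt(2 / b))
})

test_that("noise variance estimation recovers injected noise", {
  expect_identical(
    estimate_noise_variance(NULL, NULL, method = "oracle", value = 0.02), 0.02)

  # clean record whose PQ window is strictly isoelectric: essentially zero
  flat <- wave_params(
    amplitude = c(P = 0.15, Q = -0.04, R = 1, S = -0.15, T = 0.3),
    center = c(P = -1.4, Q = -0.04, R = 0, S = 0.12, T = 1.8),
    width = c(P = 0.15, Q = 0.015, R = 0.03, S = 0.03, T = 0.3))
  simf <- generate_clean(synth_spec(waves = flat, duration = 20, seed = 4))
  segf <- segment_beats(simf$truth$r_peak, n_samples(simf$record))
  expect_lt(estimate_noise_variance(simf$record, segf), 1e-8)

  # white-noise injection recovered within +/- 30% (default morphology)
  sim <- generate_clean(synth_spec(duration = 20, seed = 4))
  seg <- segment_beats(sim$truth$r_peak, n_samples(sim$record))
  out <- add_noise(sim$record, 10, seed = 6)
  v_hat <- estimate_noise_variance(out$record, seg)
  expect_lt(abs(v_hat / out$noise_var[1] - 1), 0.3)
})

test_that("the diagonal filter reproduces hand arithmetic and its limits", {
  # two-sample beat, identity map: mu_s = 2, k_x = 2, v = 1 so gain = 1/2
  ens <- make_ens(matrix(c(0, 0, 4, 4), 2, byrow = TRUE))
  model <- gp_fit(ens, noise_var = 1)   # mu = (2,2), k_diag = (4,4)
  model$k_diag <- c(2, 2)               # pin variances for the scalar check
  res <- gp_filter_beat(c(4, 4), ens$maps[[1]], model)
  expect_equal(res$posterior, c(3, 3))  # 2 + (1/2)(4 - 2)
  expect_equal(res$prior, c(2, 2))
  expect_equal(res$post_var, c(0.5, 0.5))  # k_s (1 - k_s / k_x)

  # v = 0: the measurement passes through unchanged
  model0 <- gp_fit(ens, noise_var = 0)
  x <- c(-1.3, 2.2)
  expect_equal(gp_filter_beat(x, ens$maps[[1]], model0)$posterior, x)

  # v >= max variance: full shrinkage to the prior mean
  modelb <- gp_fit(ens, noise_var = 10)
  resb <- gp_filter_beat(x, ens$maps[[1]], modelb)
  expect_equal(resb$posterior, resb$prior)
  expect_true(all(resb$gain == 0))
})

test_that("the posterior is a convex blend that shrinks monotonically", {
  set.seed(12)
  sim <- generate_clean(synth_spec(duration = 20, seed = 12))
  noisy <- add_noise(sim$record, 5, seed = 12)$record
  seg <- segment_beats(sim$truth$r_peak, n_samples(noisy))
  ens <- build_ensemble(get_lead(noisy, 1), seg)
  x <- get_lead(noisy, 1)[seg$start[3]:seg$end[3]]
  prev <- NULL
  for (v in c(0, 0.001, 0.01, 0.1, 1)) {
    model <- gp_fit(ens, noise_var = v)
    res <- gp_filter_beat(x, ens$maps[[3]], model)
    expect_true(all(res$gain >= 0 & res$gain <= 1))
    lo <- pmin(x, res$prior) - 1e-12
    hi <- pmax(x, res$prior) + 1e-12
    expect_true(all(res$posterior >= lo & res$posterior <= hi))
    expect_true(all(res$post_var >= 0))
    if (!is.null(prev)) {
      # larger v moves every sample monotonically from x toward the prior
      expect_true(all(abs(res$posterior - res$prior) <=
                        abs(prev - res$prior) + 1e-12))
    }
    prev <- res$posterior
  }
})

test_that("the full-matrix filter matches explicit matrix arithmetic", {
  # two-sample beats, identity maps: hand-buildable 2x2 system
  ens <- make_ens(matrix(c(0, 1, 2, 3, 4, 8), 3, byrow = TRUE))
  v <- 0.5
  model <- gp_fit(ens, mode = "full", noise_var = v)
  x <- c(1.5, 4)
  res <- gp_filter_beat_full(x, ens$maps[[1]], model)

  kx <- model$k_full
  ks <- kx - v * diag(2)
  mu <- model$mu
  expect_equal(res$prior, mu)
  expect_equal(res$posterior,
               as.vector(mu + ks %*% solve(kx, x - mu)), tolerance = 1e-9)

  # v = 0 passes the measurement through
  model0 <- gp_fit(ens, mode = "full", noise_var = 0)
  expect_equal(gp_filter_beat_full(x, ens$maps[[1]], model0)$posterior, x,
               tolerance = 1e-9)
})

test_that("full and diagonal paths agree when maps are one-to-one", {
  set.seed(8)
  for (i in 1:5) {
    n <- sample(4:12, 1)
    b <- sample(4:9, 1)
    beats <- matrix(rnorm(b * n), b)
    ens <- make_ens(beats)     # n_phase = n, identity-like maps
    diag_model <- gp_fit(ens)
    # keep v below every phase variance: above it the diagonal path clamps
    # the prior variance at zero while the matrix path goes negative
    v <- runif(1, 0, 0.9) * min(diag_model$k_diag)
    diag_model$noise_var <- v
    full_model <- gp_fit(ens, mode = "full", noise_var = v)
    full_model$k_full <- diag(diag_model$k_diag)  # diagonal covariance input
    x <- rnorm(n)
    a <- gp_filter_beat(x, ens$maps[[1]], diag_model)
    b2 <- gp_filter_beat_full(x, ens$maps[[1]], full_model)
    expect_equal(b2$posterior, a$posterior, tolerance = 1e-9)
    expect_equal(b2$prior, a$prior, tolerance = 1e-12)
  }
})

test_that("whole-record filtering preserves structure", {
  sim <- generate_clean(synth_spec(duration = 20, seed = 2,
                                   lead_scales = c(1, 0.6)))
  seg <- segment_beats(sim$truth$r_peak, n_samples(sim$record))

  # noiseless input with oracle v = 0: posterior equals the input exactly
  res0 <- gp_filter(sim$record, seg, noise_var = 0)
  expect_equal(res0$posterior, sim$record$samples, tolerance = 1e-12)

  # output length equals input length under RR jitter, for every output
  noisy <- add_noise(sim$record, 5, seed = 3)$record
  res <- gp_filter(noisy, seg)
  expect_equal(dim(res$posterior), dim(noisy$samples))
  expect_false(anyNA(res$posterior))
  expect_false(anyNA(res$prior))
  expect_true(all(res$post_var >= 0))

  # identical beats + noise: the prior is the warped-back noisy template
  spec_reg <- regular_spec(duration = 12)
  simr <- generate_clean(spec_reg)
  noisyr <- add_noise(simr$record, 10, seed = 5)$record
  segr <- segment_beats(simr$truth$r_peak, n_samples(noisyr))
  ensr <- build_ensemble(get_lead(noisyr, 1), segr, n_phase = 300)
  resr <- gp_filter(noisyr, segr, n_phase = 300)
  template <- colMeans(ensr$beats)
  i <- 3
  expect_equal(resr$prior[segr$start[i]:segr$end[i], 1],
               phase_backward(ensr$maps[[i]], template), tolerance = 1e-12)
})

test_that("the learned phase template converges to the clean template", {
  rmse <- sapply(c(10, 50, 200), function(nb) {
    sim <- generate_clean(synth_spec(mean_rr = 0.8, rr_jitter_sd = 0.02,
                                     amplitude_jitter_cv = 0,
                                     duration = nb * 0.8 + 1, seed = 21))
    noisy <- add_noise(sim$record, 10, seed = 22)$record
    seg <- segment_beats(sim$truth$r_peak, n_samples(noisy))
    ens <- build_ensemble(get_lead(noisy, 1), seg, n_phase = 300)
    ens_clean <- build_ensemble(get_lead(sim$record, 1), seg, n_phase = 300)
    sqrt(mean((colMeans(ens$beats) - colMeans(ens_clean$beats))^2))
  })
  expect_true(all(diff(rmse) < 0))
})
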