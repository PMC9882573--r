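#' Sum-of-Gaussians beat morphology parameters
#'
#' Each beat is modelled as five Gaussian bumps (P, Q, R, S, T) in a per-beat
#' linear phase coordinate, where one cardiac cycle spans \eqn{2\pi} radians
#' and the R peak sits at phase 0. This is the classical morphological beat
#' model used by dynamical ECG simulators, without the ODE integration.
#'
#' The defaults resemble a lead-II adult beat at ordinary resting rates:
#' a narrow QRS (Q onset about 19 ms before the R apex at RR = 0.8 s), a P
#' wave ending well before the PQ segment so that the 60-20 ms pre-R window
#' is isoelectric, and a T wave whose tangent landmark gives a QT interval
#' near 320 ms.
#'
#' @param amplitude Named numeric, wave amplitudes in mV (names P,Q,R,S,T).
#' @param center Named numeric, wave centers in radians in `[-pi, pi)`,
#'   strictly increasing, R at 0.
#' @param width Named numeric, Gaussian widths in radians, all > 0.
#'
#' @return A tibble with columns `wave`, `amplitude`, `center`, `width`.
#' @export
wave_params <- function(amplitude = c(P = 0.15, Q = -0.08, R = 1.0, S = -0.15, T = 0.30),
                        center    = c(P = -1.15, Q = -0.06, R = 0.0, S = 0.12, T = 1.80),
                        width     = c(P = 0.22, Q = 0.02, R = 0.042, S = 0.03, T = 0.30)) {
  waves <- c("P", "Q", "R", "S", "T")
  amplitude <- amplitude[waves]; center <- center[waves]; width <- width[waves]
  if (anyNA(amplitude) || anyNA(center) || anyNA(width))
    stop("wave parameters must be named P, Q, R, S, T", call. = FALSE)
  if (any(width <= 0)) stop("wave widths must be strictly positive", call. = FALSE)
  if (any(diff(center) <= 0))
    stop("wave centers must be strictly increasing in the order P < Q < R < S < T",
         call. = FALSE)
  qrs <- abs(amplitude[c("Q", "R", "S")])
  if (any(amplitude != 0) && !all(qrs["R"] > qrs[c("Q", "S")]))
    stop("R amplitude must dominate Q and S in magnitude", call. = FALSE)
  tibble::tibble(wave = waves, amplitude = unname(amplitude),
                 center = unname(center), width = unname(width))
}

#' Specification of a synthetic ECG
#'
#' Collects everything needed to generate a clean quasi-periodic ECG with
#' known ground-truth landmarks: beat morphology, RR-interval statistics,
#' per-beat amplitude variability, sampling frequency and duration.
#'
#' @param waves Beat morphology, see [wave_params()].
#' @param mean_rr Mean RR interval in seconds (> 0).
#' @param rr_jitter_sd Standard deviation of the RR interval in seconds
#'   (>= 0, must be < `mean_rr / 3`).
#' @param amplitude_jitter_cv Coefficient of variation of the per-beat
#'   amplitude scaling (>= 0).
#' @param fs Sampling frequency in Hz.
#' @param duration Record duration in seconds.
#' @param lead_scales Numeric vector of per-lead amplitude scalings; one
#'   lead per entry.
#' @param seed Integer seed; generation is deterministic given the spec.
#'
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(waves = wave_params(), mean_rr = 0.8, rr_jitter_sd = 0.04,
                       amplitude_jitter_cv = 0.03, fs = 250, duration = 60,
                       lead_scales = 1, seed = 1L) {
  stopifnot(is.data.frame(waves), nrow(waves) == 5L)
  if (mean_rr <= 0 || fs <= 0 || duration <= 0)
    stop("mean_rr, fs and duration must be positive", call. = FALSE)
  if (mean_rr * fs < 20)
    stop("mean_rr * fs must be at least 20 samples per beat", call. = FALSE)
  if (rr_jitter_sd < 0 || rr_jitter_sd >= mean_rr / 3)
    stop("rr_jitter_sd must be in [0, mean_rr / 3)", call. = FALSE)
  if (amplitude_jitter_cv < 0)
    stop("amplitude_jitter_cv must be non-negative", call. = FALSE)
  if (length(lead_scales) < 1 || any(!is.finite(lead_scales)))
    stop("lead_scales must be finite", call. = FALSE)
  structure(list(waves = waves, mean_rr = mean_rr, rr_jitter_sd = rr_jitter_sd,
                 amplitude_jitter_cv = amplitude_jitter_cv, fs = fs,
                 duration = duration, lead_scales = lead_scales,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

# Draw one RR interval, redrawing on non-positive values (max 100 redraws).
draw_rr <- function(mean_rr, sd) {
  if (sd == 0) return(mean_rr)
  for (i in 1:100) {
    rr <- stats::rnorm(1L, mean_rr, sd)
    if (rr > 0) return(rr)
  }
  stop("failed to draw a positive RR interval after 100 attempts", call. = FALSE)
}

#' Generate a clean synthetic ECG with known ground truth
#'
#' Produces a noise-free quasi-periodic ECG whose beats are sums of five
#' Gaussian bumps in a per-beat linear phase, together with the analytically
#' known landmarks needed to score downstream algorithms: R-peak sample
#' indices, Q onsets (Q center minus 3 Q widths), T offsets (T center plus
#' 2 T widths, the tangent landmark of a Gaussian T wave) and per-beat QT
#' intervals in seconds.
#'
#' RR intervals are drawn i.i.d. normal (truncated positive by redrawing),
#' each beat is scaled by an i.i.d. normal(1, cv) amplitude factor, and the
#' phase of a sample is linear in time between the midpoints flanking its R
#' peak, so beat boundaries coincide with the midpoint segmentation rule.
#'
#' @param spec A [synth_spec()].
#'
#' @return A list with elements `record` (an [ecg_record()]) and `truth`,
#'   a tibble with one row per beat: `beat`, `r_peak`, `q_onset`,
#'   `t_offset` (1-based sample indices, NA when a landmark falls outside
#'   the record) and `true_qt` (seconds).
#' @export
#' @examples
#' out <- generate_clean(synth_spec(duration = 10, seed = 7))
#' out$truth
generate_clean <- function(spec) {
  if (!inherits(spec, "synth_spec")) stop("`spec` must be a synth_spec", call. = FALSE)
  set.seed(spec$seed)
  fs <- spec$fs
  n <- round(spec$duration * fs)
  t <- (seq_len(n) - 1) / fs

  # R-peak times: first peak half an RR interval in, then cumulative RR draws,
  # keeping one peak beyond the record end to shape the final partial beat.
  rr <- draw_rr(spec$mean_rr, spec$rr_jitter_sd)
  r_times <- rr[1] / 2
  while (r_times[length(r_times)] < spec$duration) {
    rr_next <- draw_rr(spec$mean_rr, spec$rr_jitter_sd)
    rr <- c(rr, rr_next)
    r_times <- c(r_times, r_times[length(r_times)] + rr_next)
  }
  k <- length(r_times)                      # last peak is at/after duration
  amp <- stats::rnorm(k, 1, spec$amplitude_jitter_cv)

  # assign each sample to the beat whose R peak is nearest in the midpoint sense
  mids <- (r_times[-k] + r_times[-1]) / 2
  beat_of <- findInterval(t, mids) + 1L

  dt <- t - r_times[beat_of]
  # phase linear per side: left half uses the preceding RR, right half the next
  rr_prev <- rr[beat_of]
  rr_next <- c(rr[-1], spec$mean_rr)[beat_of]
  phase <- ifelse(dt < 0, 2 * pi * dt / rr_prev, 2 * pi * dt / rr_next)

  s <- numeric(n)
  for (w in seq_len(nrow(spec$waves))) {
    a <- spec$waves$amplitude[w]; c0 <- spec$waves$center[w]; wd <- spec$waves$width[w]
    if (a != 0) s <- s + a * exp(-(phase - c0)^2 / (2 * wd^2))
  }
  s <- s * amp[beat_of]

  samples <- outer(s, spec$lead_scales)
  rec <- ecg_record(samples, fs = fs)

  kept <- which(r_times < spec$duration)
  wv <- spec$waves
  q_off <- (wv$center[wv$wave == "Q"] - 3 * wv$width[wv$wave == "Q"]) / (2 * pi)
  t_off <- (wv$center[wv$wave == "T"] + 2 * wv$width[wv$wave == "T"]) / (2 * pi)
  rr_next_full <- c(rr[-1], spec$mean_rr)
  q_time <- r_times[kept] + q_off * rr[kept]
  t_time <- r_times[kept] + t_off * rr_next_full[kept]
  to_idx <- function(x) {
    i <- round(x * fs) + 1L
    ifelse(i >= 1L & i <= n, as.integer(i), NA_integer_)
  }
  truth <- tibble::tibble(
    beat = seq_along(kept),
    r_peak = to_idx(r_times[kept]),
    q_onset = to_idx(q_time),
    t_offset = to_idx(t_time),
    true_qt = t_time - q_time
  )
  list(record = rec, truth = truth)
}

#' Add white Gaussian noise at an exact signal-to-noise ratio
#'
#' Draws white Gaussian noise per lead and rescales it so that the realized
#' sample power ratio matches `snr_db` exactly (not just in expectation),
#' making SNR-dependent tests deterministic. The realized per-lead noise
#' power is returned for use as an oracle noise-variance value.
#'
#' @param record An [ecg_record()] with non-zero power in every lead
#'   (unless `snr_db` is infinite).
#' @param snr_db Target signal-to-noise ratio in dB; `Inf` returns the
#'   record unchanged.
#' @param seed Integer seed.
#'
#' @return A list with `record` (noisy copy) and `noise_var`, the named
#'   per-lead realized noise power (mean squared noise sample).
#' @export
add_noise <- function(record, snr_db, seed = 1L) {
  stopifnot(inherits(record, "ecg_record"))
  if (is.infinite(snr_db) && snr_db > 0) {
    nv <- stats::setNames(numeric(n_leads(record)), record$lead_names)
    return(list(record = record, noise_var = nv))
  }
  set.seed(as.integer(seed))
  out <- record$samples
  nv <- numeric(ncol(out))
  for (j in seq_len(ncol(out))) {
    x <- out[, j]
    p_sig <- mean(x^2)
    if (p_sig == 0)
      stop("lead ", j, " has zero power; finite snr_db is undefined", call. = FALSE)
    p_noise <- p_sig * 10^(-snr_db / 10)
    z <- stats::rnorm(length(x))
    z <- z * sqrt(p_noise / mean(z^2))
    out[, j] <- x + z
    nv[j] <- p_noise
  }
  names(nv) <- record$lead_names
  list(record = set_samples(record, out), noise_var = nv)
}

#' Add low-frequency baseline wander
#'
#' Adds a sinusoidal drift plus a normalized random-walk component to every
#' lead, emulating respiration- and motion-related baseline wander.
#'
#' @param record An [ecg_record()].
#' @param amplitude Peak drift amplitude in mV; 0 is the identity.
#' @param freq Sinusoid frequency in Hz (typically < 1 Hz).
#' @param seed Integer seed (random phase and walk).
#'
#' @return The drifted [ecg_record()].
#' @export
add_baseline_wander <- function(record, amplitude = 0.5, freq = 0.3, seed = 1L) {
  stopifnot(inherits(record, "ecg_record"))
  if (amplitude == 0) return(record)
  set.seed(as.integer(seed))
  n <- n_samples(record)
  t <- (seq_len(n) - 1) / record$fs
  phi0 <- stats::runif(1, 0, 2 * pi)
  rw <- cumsum(stats::rnorm(n))
  rw <- rw - mean(rw)
  mx <- max(abs(rw))
  if (mx > 0) rw <- rw / mx
  drift <- amplitude * sin(2 * pi * freq * t + phi0) + 0.25 * amplitude * rw
  set_samples(record, record$samples + drift)
}
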