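#' Warp all beats of a record onto a common phase axis
#'
#' Builds one warping map per beat and stacks the warped beats into a
#' `B x n_phase` matrix (the phase ensemble). With R-aligned maps (the
#' default) every row has its R peak at the same phase column, so the rows
#' can be treated as draws from one phase-domain process.
#'
#' The common R phase index is chosen once per record as
#' `round(n_phase * median(r_offset / n_i))`, clamped to the feasible range
#' implied by the longest pre-R and post-R segments.
#'
#' @param signal Numeric vector, one lead of a record.
#' @param seg A [segment_beats()] result covering the signal.
#' @param n_phase Number of phase samples; `NULL` (default) uses
#'   `ceiling(1.1 * max(n_i))`, 10% headroom over the longest beat. Must be
#'   at least `max(n_i)`.
#' @param alignment `"r_aligned"` (two-segment maps, default) or
#'   `"single"` (plain equidistant-knot maps, no R alignment).
#'
#' @return A list of class `phase_ensemble`: `beats` (B x n_phase matrix),
#'   `maps` (per-beat [phase_map()]s), `n_phase`, `r_phase`, `seg`.
#' @export
build_ensemble <- function(signal, seg, n_phase = NULL,
                           alignment = c("r_aligned", "single")) {
  alignment <- match.arg(alignment)
  stopifnot(inherits(seg, "beat_segmentation"))
  b <- nrow(seg)
  if (b < 2) stop("GP filter requires multiple beats (got ", b, ")", call. = FALSE)
  n_i <- seg$n_i
  if (is.null(n_phase)) {
    span <- max(n_i)
    if (alignment == "r_aligned")
      span <- max(span, max(seg$r_offset) + max(n_i - seg$r_offset + 1L))
    n_phase <- as.integer(ceiling(1.1 * span))
  }
  if (n_phase < max(n_i)) {
    worst <- which.max(n_i)
    stop("beat ", worst, " has ", n_i[worst],
         " samples, longer than n_phase = ", n_phase, call. = FALSE)
  }

  r_phase <- NA_integer_
  if (alignment == "r_aligned") {
    n_pre <- seg$r_offset - 1L
    n_post <- n_i - n_pre
    lo <- max(n_pre) + 1L
    hi <- n_phase - max(n_post) + 1L
    if (lo > hi)
      stop("no feasible common R phase index; increase n_phase (need >= ",
           max(n_pre) + max(n_post), ")", call. = FALSE)
    r_phase <- as.integer(round(n_phase * stats::median(seg$r_offset / n_i)))
    r_phase <- min(max(r_phase, lo), hi)
    maps <- lapply(seq_len(b), function(i)
      phase_map_r_aligned(n_pre[i], n_post[i], n_phase, r_phase))
  } else {
    maps <- lapply(seq_len(b), function(i) phase_map(n_i[i], n_phase))
  }

  beats <- matrix(NA_real_, b, n_phase)
  for (i in seq_len(b))
    beats[i, ] <- phase_forward(maps[[i]], signal[seg$start[i]:seg$end[i]])
  structure(list(beats = beats, maps = maps, n_phase = as.integer(n_phase),
                 r_phase = r_phase, seg = seg),
            class = "phase_ensemble")
}

#' @export
print.phase_ensemble <- function(x, ...) {
  cat(sprintf("<phase_ensemble> %d beats x %d phase samples%s\n",
              nrow(x$beats), x$n_phase,
              if (!is.na(x$r_phase)) sprintf(" (R at phase %d)", x$r_phase) else ""))
  invisible(x)
}

#' Fit the phase-domain Gaussian process model
#'
#' Estimates the phase-domain mean and covariance of the warped beats by
#' their sample statistics (1/B normalization, matching the generative
#' reading of the ensemble; `cov_norm = "B-1"` switches to the unbiased
#' form). In diagonal mode only the per-phase variances are kept; full mode
#' retains the complete sample covariance for the matrix-form filter.
#'
#' @param ens A [build_ensemble()] result.
#' @param mode `"diagonal"` (default) or `"full"`.
#' @param noise_var Measurement noise variance estimate (mV^2); see
#'   [estimate_noise_variance()]. May be left `NULL` and supplied later.
#' @param cov_norm `"B"` (default) or `"B-1"`.
#'
#' @return An object of class `gp_model`: `mu` (phase mean), `k_diag`
#'   (phase variances), `k_full` (covariance matrix, full mode only),
#'   `noise_var`, `mode`, `n_phase`, `r_phase`, `n_beats`.
#' @export
gp_fit <- function(ens, mode = c("diagonal", "full"), noise_var = NULL,
                   cov_norm = c("B", "B-1")) {
  mode <- match.arg(mode)
  cov_norm <- match.arg(cov_norm)
  stopifnot(inherits(ens, "phase_ensemble"))
  b <- nrow(ens$beats)
  if (b < 2) stop("need at least 2 beats to fit", call. = FALSE)
  denom <- if (cov_norm == "B") b else b - 1L
  mu <- colMeans(ens$beats)
  xc <- sweep(ens$beats, 2, mu)
  k_full <- NULL
  if (mode == "full") {
    k_full <- crossprod(xc) / denom
    k_diag <- diag(k_full)
  } else {
    k_diag <- colSums(xc^2) / denom
  }
  if (!is.null(noise_var)) {
    stopifnot(is.numeric(noise_var), length(noise_var) == 1L, noise_var >= 0)
  }
  structure(list(mu = mu, k_diag = k_diag, k_full = k_full,
                 noise_var = noise_var, mode = mode,
                 n_phase = ens$n_phase, r_phase = ens$r_phase, n_beats = b),
            class = "gp_model")
}

#' @export
print.gp_model <- function(x, ...) {
  cat(sprintf("<gp_model> %s, %d beats, %d phase samples, noise_var = %s\n",
              x$mode, x$n_beats, x$n_phase,
              if (is.null(x$noise_var)) "unset" else format(x$noise_var)))
  invisible(x)
}

#' Estimate the measurement noise variance
#'
#' The `"baseline"` method uses the isoelectric segment of each beat, where
#' the heart is electrically silent and only noise is present: it takes a
#' window before each R peak (default 60 to 20 ms), detrends it (quadratic
#' fit, so slow drift and wave tails do not masquerade as noise) and
#' averages the residual variances across beats. The `"oracle"` method
#' simply returns a caller-supplied known variance (for simulation work).
#'
#' @param record An [ecg_record()] (pre-filtering, or whatever signal the
#'   GP filter will see).
#' @param seg A [segment_beats()] result.
#' @param method `"baseline"` or `"oracle"`.
#' @param lead Lead to estimate from.
#' @param window Two positive numbers, seconds before the R peak bounding
#'   the isoelectric window (default `c(0.060, 0.020)`).
#' @param value Known variance for `method = "oracle"`.
#' @param band `NULL` (default) when the noise can be treated as white, or
#'   the preprocessing passband `c(fc_low, fc_high)` in Hz when the record
#'   has been band-limited by [remove_baseline()]. Band-limited noise is
#'   correlated, so the detrending fit absorbs part of its power; the known
#'   filter shapes let that absorbed fraction be computed exactly (a trace
#'   identity over the noise autocorrelation) and undone.
#'
#' @return A single non-negative noise variance (mV^2).
#' @export
estimate_noise_variance <- function(record, seg, method = c("baseline", "oracle"),
                                    lead = 1L, window = c(0.060, 0.020),
                                    value = NULL, band = NULL) {
  method <- match.arg(method)
  if (method == "oracle") {
    if (is.null(value)) stop("oracle method needs `value`", call. = FALSE)
    return(as.numeric(value))
  }
  stopifnot(inherits(record, "ecg_record"), inherits(seg, "beat_segmentation"))
  x <- get_lead(record, lead)
  fs <- record$fs
  off <- round(window * fs)
  if (off[1] <= off[2]) stop("window must be ordered (far, near) before R", call. = FALSE)
  vars <- vapply(seq_len(nrow(seg)), function(i) {
    lo <- seg$r_peak[i] - off[1]
    hi <- seg$r_peak[i] - off[2]
    if (lo < seg$start[i] || lo < 1 || hi - lo + 1 < 5) return(NA_real_)
    w <- x[lo:hi]
    m <- length(w)
    # detrend with a quadratic fit so residual baseline drift and wave tails
    # do not inflate the estimate; n/(n-p) corrects the fit's absorbed df
    tt <- seq_len(m)
    r <- stats::lm.fit(cbind(1, tt, tt^2), w)$residuals
    sum(r^2) / (m - 3)
  }, numeric(1))
  vars <- vars[!is.na(vars)]
  if (length(vars) == 0)
    stop("no beat had a usable isoelectric window", call. = FALSE)
  v <- mean(vars)
  if (!is.null(band)) {
    m <- off[1] - off[2] + 1L
    v <- v / detrend_absorption(m, band[1], band[2], fs)
  }
  v
}

# Expected fraction of band-limited noise power surviving a quadratic
# detrend on an m-sample window: E[RSS/(m-3)] = v * tr((I - H) R) / (m - 3),
# with R the Toeplitz autocorrelation of white noise pushed through the
# zero-phase band filters. Deterministic: computed from the filters'
# impulse response, no data involved.
detrend_absorption <- function(m, fc_low, fc_high, fs) {
  n <- 4096L
  imp <- numeric(n)
  imp[n %/% 2L] <- 1
  h <- band_filter_vec(imp, fc_low, fc_high, fs)
  r0 <- sum(h^2)
  rho <- vapply(0:(m - 1L), function(tau)
    sum(h[seq_len(n - tau)] * h[(1L + tau):n]) / r0, numeric(1))
  r_mat <- stats::toeplitz(rho)
  tt <- seq_len(m)
  xmat <- cbind(1, tt, tt^2)
  hat <- xmat %*% solve(crossprod(xmat), t(xmat))
  sum(diag((diag(m) - hat) %*% r_mat)) / (m - 3)
}

#' Filter one beat with the diagonal-covariance GP filter
#'
#' The matrix-free form of the posterior-mean filter. With `assign` the
#' knot assignment and `g` the Gramian diagonal of the beat's map, the
#' time-domain quantities are bin-averages of the phase-domain statistics:
#' prior mean `mu_s = backward(mu)`, measurement variance
#' `k_x = binsum(k_diag) / g^2`, prior variance
#' `k_s = binsum(k_diag - noise_var) / g^2` clamped at 0, and the filtered
#' beat is `mu_s + (k_s / k_x) * (x - mu_s)` with the gain defined as 0
#' wherever `k_x = 0`. The per-sample posterior variance
#' `k_s * (1 - k_s / k_x)` quantifies the filter's confidence.
#'
#' @param x Numeric beat vector of length `map$n_time`.
#' @param map The beat's [phase_map()].
#' @param model A diagonal-mode [gp_fit()] with `noise_var` set.
#'
#' @return A list with `posterior`, `prior` (the back-warped phase mean),
#'   `post_var` and `gain`, all of length `map$n_time`.
#' @export
gp_filter_beat <- function(x, map, model) {
  stopifnot(inherits(map, "phase_map"), inherits(model, "gp_model"))
  if (model$mode != "diagonal") stop("model must be diagonal mode", call. = FALSE)
  if (is.null(model$noise_var)) stop("model$noise_var is unset", call. = FALSE)
  if (length(x) != map$n_time) stop("beat length does not match map", call. = FALSE)
  g <- map$g
  binsum <- function(v) as.vector(rowsum(v, map$assign, reorder = TRUE))
  mu_s <- binsum(model$mu) / g
  s_k <- binsum(model$k_diag)
  k_x <- s_k / g^2
  k_s <- pmax(0, (s_k - model$noise_var * g) / g^2)
  gain <- ifelse(k_x > 0, k_s / k_x, 0)
  posterior <- mu_s + gain * (x - mu_s)
  post_var <- k_s * (1 - gain)
  list(posterior = posterior, prior = mu_s, post_var = post_var, gain = gain)
}

# Bin-aggregate rows and columns of a phase-domain matrix down to the time
# domain: Psi %*% K %*% t(Psi) computed without materializing Theta.
psi_sandwich <- function(k_full, map) {
  m1 <- rowsum(k_full, map$assign, reorder = TRUE)          # N x T
  m2 <- t(rowsum(t(m1), map$assign, reorder = TRUE))        # N x N
  m2 / outer(map$g, map$g)
}

#' Filter one beat with the full-covariance GP filter
#'
#' The matrix form of the posterior-mean filter: the phase covariance is
#' pushed through the back transformation to give the time-domain
#' measurement covariance `K_x`, the prior covariance is `K_x` minus the
#' noise variance on the diagonal (the back transformation maps the
#' replicated phase noise onto the identity), and the posterior mean solves
#' a linear system rather than inverting. Sample covariances of warped
#' beats are typically badly conditioned, so a small ridge jitter
#' (1e-10 of the mean diagonal, doubled up to 6 times) is added when the
#' solve fails.
#'
#' Intended for modest beat lengths (validation and oracle use); the
#' diagonal path is the production filter.
#'
#' @inheritParams gp_filter_beat
#' @param model A full-mode [gp_fit()] with `noise_var` set.
#'
#' @return A list with `posterior`, `prior`, `post_var` (diagonal of the
#'   posterior covariance) and `k_post` (full posterior covariance).
#' @export
gp_filter_beat_full <- function(x, map, model) {
  stopifnot(inherits(map, "phase_map"), inherits(model, "gp_model"))
  if (model$mode != "full" || is.null(model$k_full))
    stop("model must be full mode", call. = FALSE)
  if (is.null(model$noise_var)) stop("model$noise_var is unset", call. = FALSE)
  if (length(x) != map$n_time) stop("beat length does not match map", call. = FALSE)
  n <- map$n_time
  mu_s <- as.vector(rowsum(model$mu, map$assign, reorder = TRUE)) / map$g
  k_x <- psi_sandwich(model$k_full, map)
  k_s <- k_x - model$noise_var * diag(n)
  base <- 1e-10 * mean(diag(k_x))
  sol <- NULL
  for (i in 0:6) {
    jitter <- if (i == 0) 0 else base * 2^(i - 1)
    sol <- tryCatch({
      kxj <- k_x + jitter * diag(n)
      list(gain_t = solve(kxj, t(k_s)), kxj = kxj)
    }, error = function(e) NULL)
    if (!is.null(sol)) break
  }
  if (is.null(sol))
    stop("measurement covariance numerically singular after maximum jitter",
         call. = FALSE)
  resid <- x - mu_s
  posterior <- mu_s + as.vector(crossprod(sol$gain_t, resid))
  k_post <- k_s - k_s %*% solve(sol$kxj, k_s)
  list(posterior = posterior, prior = mu_s,
       post_var = pmax(0, diag(k_post)), k_post = k_post)
}

#' Denoise a whole record with the phase-domain GP filter
#'
#' The end-to-end filter: per lead, warp the segmented beats onto the
#' common phase axis, fit the phase-domain sample mean and (co)variance,
#' estimate the noise variance, filter every beat and concatenate the
#' results (the beats partition the record, so lengths are preserved).
#' Both the prior-based result (the back-warped beat template) and the
#' posterior-based result (template and measurement blended per sample by
#' signal-versus-noise variance) are returned, along with the per-sample
#' posterior variance.
#'
#' @param record An [ecg_record()], already baseline-removed (see
#'   [remove_baseline()]).
#' @param seg A [segment_beats()] result for this record.
#' @param n_phase,alignment Passed to [build_ensemble()].
#' @param mode `"diagonal"` (default, matrix-free) or `"full"`.
#' @param noise_var Known noise variance: a single value, or one per lead;
#'   `NULL` (default) estimates it per lead with the baseline method.
#' @param noise_band Passband `c(fc_low, fc_high)` assumed for the
#'   baseline noise estimate (see [estimate_noise_variance()]); defaults
#'   to the standard preprocessing band `c(5, 80)`. Set `NULL` for white
#'   (unfiltered) noise.
#' @param cov_norm Passed to [gp_fit()].
#'
#' @return An object of class `gp_filter_result`: `prior`, `posterior`,
#'   `post_var` (numeric matrices, samples x leads), `models` (per-lead
#'   [gp_fit()] objects), `seg`, `record` (the input), `fs`.
#' @export
#' @examples
#' sim <- generate_clean(synth_spec(duration = 20, seed = 2))
#' noisy <- add_noise(sim$record, snr_db = 5, seed = 3)$record
#' seg <- segment_beats(sim$truth$r_peak, n_samples(noisy))
#' res <- gp_filter(noisy, seg, noise_var = 0.002)
#' res
gp_filter <- function(record, seg, n_phase = NULL,
                      alignment = c("r_aligned", "single"),
                      mode = c("diagonal", "full"), noise_var = NULL,
                      noise_band = c(5, 80), cov_norm = c("B", "B-1")) {
  alignment <- match.arg(alignment)
  mode <- match.arg(mode)
  cov_norm <- match.arg(cov_norm)
  stopifnot(inherits(record, "ecg_record"), inherits(seg, "beat_segmentation"))
  if (attr(seg, "n_total") != n_samples(record))
    stop("segmentation does not match record length", call. = FALSE)
  nl <- n_leads(record)
  if (!is.null(noise_var) && !(length(noise_var) %in% c(1L, nl)))
    stop("noise_var must be a single value or one per lead", call. = FALSE)

  n <- n_samples(record)
  prior <- posterior <- post_var <- matrix(NA_real_, n, nl,
                                           dimnames = list(NULL, record$lead_names))
  models <- vector("list", nl)
  for (j in seq_len(nl)) {
    x <- get_lead(record, j)
    ens <- build_ensemble(x, seg, n_phase = n_phase, alignment = alignment)
    v <- if (is.null(noise_var)) {
      estimate_noise_variance(record, seg, method = "baseline", lead = j,
                              band = noise_band)
    } else if (length(noise_var) == 1L) noise_var else noise_var[j]
    model <- gp_fit(ens, mode = mode, noise_var = v, cov_norm = cov_norm)
    models[[j]] <- model
    for (i in seq_len(nrow(seg))) {
      idx <- seg$start[i]:seg$end[i]
      res <- tryCatch({
        if (mode == "diagonal") gp_filter_beat(x[idx], ens$maps[[i]], model)
        else gp_filter_beat_full(x[idx], ens$maps[[i]], model)
      }, error = function(e) {
        stop("lead ", j, ", beat ", i, ": ", conditionMessage(e), call. = FALSE)
      })
      prior[idx, j] <- res$prior
      posterior[idx, j] <- res$posterior
      post_var[idx, j] <- res$post_var
    }
  }
  structure(list(prior = prior, posterior = posterior, post_var = post_var,
                 models = models, seg = seg, record = record, fs = record$fs),
            class = "gp_filter_result")
}

#' @export
print.gp_filter_result <- function(x, ...) {
  cat(sprintf("<gp_filter_result> %d samples x %d lead(s), %d beats, %s GP\n",
              nrow(x$posterior), ncol(x$posterior), nrow(x$seg),
              x$models[[1]]$mode))
  invisible(x)
}

#' Extract a filtered lead as an ecg_record
#'
#' @param result A [gp_filter()] result.
#' @param what `"posterior"` (default) or `"prior"`.
#' @return An [ecg_record()] with the same leads and fs as the input.
#' @export
filtered_record <- function(result, what = c("posterior", "prior")) {
  what <- match.arg(what)
  stopifnot(inherits(result, "gp_filter_result"))
  ecg_record(result[[what]], fs = result$fs,
             lead_names = result$record$lead_names)
}
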