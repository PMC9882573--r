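#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the phase-domain GP model
#'
#' One row per phase sample: the learned template mean, the phase variance
#' and its square root.
#'
#' @param x A [gp_fit()] object.
#' @param ... Unused.
#' @return A tibble with columns `phase`, `mean`, `variance`, `sd`.
#' @export
tidy.gp_model <- function(x, ...) {
  tibble::tibble(phase = seq_len(x$n_phase), mean = x$mu,
                 variance = x$k_diag, sd = sqrt(pmax(x$k_diag, 0)))
}

#' One-row summary of a fitted GP model
#'
#' @param x A [gp_fit()] object.
#' @param ... Unused.
#' @return A tibble with `n_beats`, `n_phase`, `r_phase`, `mode`,
#'   `noise_var` and `mean_phase_var`.
#' @export
glance.gp_model <- function(x, ...) {
  tibble::tibble(n_beats = x$n_beats, n_phase = x$n_phase,
                 r_phase = x$r_phase, mode = x$mode,
                 noise_var = ifelse(is.null(x$noise_var), NA_real_, x$noise_var),
                 mean_phase_var = mean(x$k_diag))
}

#' Tidy a GP filter result
#'
#' Long-format table of the filtered record: one row per sample and lead
#' with the measurement, prior, posterior and posterior variance.
#'
#' @param x A [gp_filter()] result.
#' @param ... Unused.
#' @return A tibble with `time_s`, `lead`, `measurement`, `prior`,
#'   `posterior`, `post_var`.
#' @export
tidy.gp_filter_result <- function(x, ...) {
  n <- nrow(x$posterior)
  leads <- colnames(x$posterior)
  purrr::map_dfr(seq_along(leads), function(j) {
    tibble::tibble(
      time_s = (seq_len(n) - 1) / x$fs,
      lead = leads[j],
      measurement = x$record$samples[, j],
      prior = x$prior[, j],
      posterior = x$posterior[, j],
      post_var = x$post_var[, j])
  })
}

#' One-row-per-lead summary of a GP filter result
#'
#' @param x A [gp_filter()] result.
#' @param ... Unused.
#' @return A tibble with `lead`, `n_beats`, `n_phase`, `noise_var` and
#'   `mean_post_var`.
#' @export
glance.gp_filter_result <- function(x, ...) {
  leads <- colnames(x$posterior)
  purrr::map_dfr(seq_along(leads), function(j) {
    m <- x$models[[j]]
    tibble::tibble(lead = leads[j], n_beats = m$n_beats, n_phase = m$n_phase,
                   noise_var = m$noise_var,
                   mean_post_var = mean(x$post_var[, j]))
  })
}
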