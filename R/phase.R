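# Equidistant-knot assignment of n_phase phase knots onto n_time samples:
# phase knot k maps to time index floor((k-1)(N-1)/(T-1)) + 1, the last knot
# closing on j = N so every time index receives at least one knot and the
# Gramian stays invertible. Integer arithmetic throughout.
knot_assign <- function(n_time, n_phase) {
  if (n_time == 1L) return(rep(1L, n_phase))
  k <- seq_len(n_phase)
  as.integer(((k - 1) * (n_time - 1)) %/% (n_phase - 1) + 1)
}

new_phase_map <- function(assign, n_time, n_phase, r_phase = NA_integer_) {
  g <- tabulate(assign, nbins = n_time)
  if (any(g < 1))
    stop("internal error: unassigned time index (singular Gramian)", call. = FALSE)
  structure(list(n_time = as.integer(n_time), n_phase = as.integer(n_phase),
                 assign = as.integer(assign), g = as.integer(g),
                 r_phase = as.integer(r_phase)),
            class = "phase_map")
}

#' Build a time-to-phase warping map
#'
#' Constructs the sparse content of a beat's binary time-to-phase
#' transformation: `n_phase` knots equidistantly distributed over the
#' `n_time` samples, each phase index pointing at exactly one time index.
#' Requires `n_phase >= n_time` so that every time sample receives at least
#' one knot, making the (diagonal) Gramian invertible and the
#' time-phase-time round trip exact.
#'
#' @param n_time Beat length in samples (>= 2).
#' @param n_phase Number of phase samples (>= `n_time`).
#'
#' @return A `phase_map`: list with `n_time`, `n_phase`, `assign` (time
#'   index for each phase index, non-decreasing), `g` (per-time-index knot
#'   counts, the Gramian diagonal) and `r_phase` (NA for this single-segment
#'   variant).
#' @export
#' @examples
#' m <- phase_map(3, 5)
#' m$assign  # 1 1 2 2 3
#' m$g       # 2 2 1
phase_map <- function(n_time, n_phase) {
  if (n_time < 2) stop("n_time must be at least 2", call. = FALSE)
  if (n_phase < n_time)
    stop("n_phase must be >= n_time (Gramian would be singular)", call. = FALSE)
  new_phase_map(knot_assign(n_time, n_phase), n_time, n_phase)
}

#' Build an R-aligned two-segment warping map
#'
#' Applies the equidistant-knot rule independently to the pre-R and post-R
#' segments of a beat so that the R-peak sample maps exactly to the fixed
#' phase index `r_phase` in every beat of a record. This is what makes the
#' warped beats an ensemble of one process: equal length and aligned R
#' peaks.
#'
#' @param n_pre Number of samples strictly before the R peak.
#' @param n_post Number of samples from the R peak to the end of the beat
#'   (inclusive), so the beat length is `n_pre + n_post`.
#' @param n_phase Total number of phase samples.
#' @param r_phase Phase index the R peak maps to. Requires
#'   `r_phase >= n_pre + 1` and `n_phase - r_phase >= n_post - 1`.
#'
#' @return A `phase_map` with `r_phase` set.
#' @export
#' @examples
#' m <- phase_map_r_aligned(2, 3, 7, 3)
#' m$assign           # 1 2 3 3 4 4 5
#' m$assign[3]        # the R peak (time index 3) at phase 3
phase_map_r_aligned <- function(n_pre, n_post, n_phase, r_phase) {
  n_time <- n_pre + n_post
  if (n_post < 1) stop("n_post must be at least 1", call. = FALSE)
  if (n_time < 2) stop("beat must have at least 2 samples", call. = FALSE)
  if (r_phase < n_pre + 1)
    stop("r_phase too small for the pre-R segment (need r_phase >= n_pre + 1)",
         call. = FALSE)
  if (n_phase - r_phase < n_post - 1)
    stop("n_phase - r_phase too small for the post-R segment", call. = FALSE)
  pre <- knot_assign(n_pre + 1L, r_phase)            # phases 1..r_phase -> 1..n_pre+1
  post <- knot_assign(n_post, n_phase - r_phase + 1L) # phases r_phase..T -> R..end
  assign <- c(pre[seq_len(r_phase - 1L)], n_pre + post)
  new_phase_map(assign, n_time, n_phase, r_phase = r_phase)
}

#' @export
print.phase_map <- function(x, ...) {
  cat(sprintf("<phase_map> %d time samples -> %d phase samples%s\n",
              x$n_time, x$n_phase,
              if (!is.na(x$r_phase)) sprintf(" (R at phase %d)", x$r_phase) else ""))
  invisible(x)
}

#' Warp a time-domain beat to the phase domain
#'
#' Pure sample replication (a gather): phase sample `k` takes the value of
#' time sample `assign[k]`. No interpolation is involved, which is what
#' makes the round trip through [phase_backward()] exact.
#'
#' @param map A [phase_map()].
#' @param x Numeric vector of length `map$n_time`.
#'
#' @return Numeric vector of length `map$n_phase`.
#' @export
phase_forward <- function(map, x) {
  stopifnot(inherits(map, "phase_map"))
  if (length(x) != map$n_time)
    stop("length(x) must equal map$n_time (", map$n_time, ")", call. = FALSE)
  x[map$assign]
}

#' Warp a phase-domain beat back to the time domain
#'
#' The scatter-average inverse of [phase_forward()]: each time sample is the
#' mean of the phase samples assigned to it, which equals the Gramian-
#' normalized adjoint applied to the phase vector. Composed with
#' [phase_forward()] it is the identity on time-domain vectors.
#'
#' @param map A [phase_map()].
#' @param xi Numeric vector of length `map$n_phase`.
#'
#' @return Numeric vector of length `map$n_time`.
#' @export
phase_backward <- function(map, xi) {
  stopifnot(inherits(map, "phase_map"))
  if (length(xi) != map$n_phase)
    stop("length(xi) must equal map$n_phase (", map$n_phase, ")", call. = FALSE)
  as.vector(rowsum(xi, map$assign, reorder = TRUE)) / map$g
}

#' Materialize the dense transformation matrix of a map
#'
#' Builds the full binary `n_phase x n_time` matrix whose row `k` has a
#' single 1 in column `assign[k]`. Intended for inspection, debugging and
#' as the dense oracle in tests; production paths never materialize it.
#'
#' @param map A [phase_map()].
#' @return A dense 0/1 matrix with `n_phase` rows and `n_time` columns.
#' @export
theta_matrix <- function(map) {
  stopifnot(inherits(map, "phase_map"))
  m <- matrix(0, map$n_phase, map$n_time)
  m[cbind(seq_len(map$n_phase), map$assign)] <- 1
  m
}
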