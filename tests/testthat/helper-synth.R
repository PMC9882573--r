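# Shared fixtures, all generated in code.

# Short regular record: no jitter, analytic layout.
regular_spec <- function(duration = 10, fs = 250) {
  synth_spec(mean_rr = 1, rr_jitter_sd = 0, amplitude_jitter_cv = 0,
             fs = fs, duration = duration, seed = 11L)
}

# The study-condition record: 60 s, two leads, default variability.
study_sim <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) memo <<- generate_clean(
      synth_spec(seed = 42L, lead_scales = c(1, 0.7)))
    memo
  }
})

# Dense transformation matrix built literally from the knot inequality
# j - 1 <= (k - 1)(N - 1)/(T - 1) < j, independent of the package's
# assignment-vector construction.
dense_theta_oracle <- function(n_time, n_phase) {
  m <- matrix(0, n_phase, n_time)
  for (k in seq_len(n_phase)) {
    q <- (k - 1) * (n_time - 1) / (n_phase - 1)
    for (j in seq_len(n_time)) {
      if (j - 1 <= q && q < j) m[k, j] <- 1
    }
    if (k == n_phase) m[k, n_time] <- 1  # q = N - 1 falls on the closing knot
  }
  m
}
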