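# gpecg

Data-driven Gaussian process filtering for ECG denoising.

Wearable and clinical ECG recordings carry in-band noise that ordinary
band filters cannot remove without destroying the waveform. Gaussian
process (GP) filters can, but a GP prior placed directly on the signal
needs hand-picked mean and kernel functions and an `O(N^3)` solve that
rules out long records. `gpecg` implements a phase-domain GP filter that
has neither problem: it is for signal-processing researchers and ECG
methodologists who want a principled beat-wise Bayesian denoiser with no
ad hoc hyperparameters, plus the harness to evaluate it.

## The method

The record is segmented into beats at the midpoints between successive R
peaks. Each beat `x_i` (length `N_i`) is warped onto a fixed phase length
`T >= max N_i` by a sparse binary matrix `Θ_i` (one 1 per row, knots
equidistant over the beat, R peaks aligned at a common phase index):

    ξ_i = Θ_i x_i,        G_i = Θ_iᵀ Θ_i = diag(g_i),
    Ψ_i = G_i⁻¹ Θ_iᵀ      (back-transform; Ψ_i Θ_i = I, exact round trip)

The warped beats are modelled as draws from one Gaussian process,
`ξ_i ~ N(μ_ξ, K_ξ)`, whose mean and covariance are estimated by the
phase-domain *sample* mean and covariance over the B beats — the data are
the prior. With a noise-variance estimate `v̂_n` taken from the
isoelectric PQ segment, the filtered beat is the Gaussian posterior mean

    ŝ_i = μ_si + K_si K_xi⁻¹ (x_i − μ_si),   μ_si = Ψ_i μ̄_ξ

and in the production (diagonal-covariance) form everything reduces to
per-sample gains `k_s ⊘ k_x ∈ [0, 1]` — no matrix is ever inverted, the
cost is `O(T)` per beat, and a per-sample posterior variance quantifies
the filter's confidence. Both the *prior-based* output (the back-warped
beat template) and the *posterior-based* output are returned.

The package also ships the surrounding tooling: zero-phase baseline-wander
removal (subtract 5 Hz lowpass, then 80 Hz lowpass), a modified
Pan-Tompkins R-peak detector (bandpass, tanh saturation, energy envelope,
adaptive threshold), a Symlet-5 SURE soft-threshold wavelet denoiser as
the benchmark, a synthetic ECG generator with analytically known R/Q/T
landmarks, and an SNR-improvement / QT-error evaluation grid.

## Worked example

```r
library(gpecg)

sim   <- generate_clean(synth_spec(duration = 60, seed = 42,
                                   lead_scales = c(1, 0.7)))
noisy <- add_noise(sim$record, snr_db = 5, seed = 1)$record

pre <- remove_baseline(noisy)                      # 5-80 Hz, zero phase
seg <- segment_beats(detect_rpeaks(pre), n_samples(pre))
fit <- gp_filter(pre, seg)                         # diagonal GP filter
fit
#> <gp_filter_result> 15000 samples x 2 lead(s), 75 beats, diagonal GP
glance(fit)
#> # A tibble: 2 × 5
#>   lead  n_beats n_phase noise_var mean_post_var
#>   <chr>   <int>   <int>     <dbl>         <dbl>
#> 1 lead1      75     247   0.00299     0.000105
#> 2 lead2      75     247   0.00137     0.0000676
```

75 beats were detected and warped onto 247 phase samples; the PQ-segment
noise estimate for lead 1 is 0.0030 mV², and the mean posterior variance —
the filter's own uncertainty about the clean signal — is thirty times
smaller. Measured against the clean record, the posterior improves the
SNR of this 5 dB input by 12.8 dB. `tidy(fit)` returns the
sample-by-sample table, `autoplot(fit)` plots the posterior with its
confidence band, and `filtered_record(fit)` extracts the denoised record.

The full experiment grid (paired noise instances per method, fully seeded):

```r
bench <- run_benchmark_grid(sim$record, reps = 2, seed0 = 1)
summarise_snr(bench)
#> # A tibble: 24 × 5
#>    input_snr_db method    mean_db  sd_db     n
#>           <dbl> <chr>       <dbl>  <dbl> <int>
#>  1           -5 posterior  10.3   0.661      4
#>  2           -5 prior       8.18  0.479      4
#>  3           -5 wavelet     2.23  0.0887     4
#>  4            0 posterior  13.4   0.822      4
#>  ...
#> 22           30 posterior   3.27  0.0474     4
#> 23           30 prior     -15.1   0.0220     4
#> 24           30 wavelet     1.50  0.129      4
```

The posterior improves the SNR at every level and dominates both the
prior (which collapses at high input SNR, where the template's own bias
exceeds the noise) and the wavelet benchmark. `plot_snr_improvement()`
and `plot_delta_qt()` draw the summary figures; `summarise_qt()` gives
the QT-interval error medians and IQRs.

A thin command-line front end over the same functions is installed at
`inst/cli/gpecg.R` (`simulate`, `filter`, `benchmark`, `inspect`).

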