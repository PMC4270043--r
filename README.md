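# synquant

Optical quantal analysis of single synaptic vesicle fusion events in
fluorescence time series.

Synaptic vesicles fused with pH-sensitive probes (vGlut1-pHluorin,
synaptophysin-pHTomato) report individual fusion events as small, rapid
increases in bouton fluorescence that decay as the vesicle is retrieved and
re-acidified. `synquant` is for experimenters who have such per-ROI traces
(or dual-channel recordings with a postsynaptic GCaMP Ca²⁺ reporter) and
want to go from raw traces to quantal statistics:

- **Detection** — an event is called at frame *f* when the 3-point average
  rise exceeds twice the SD of the 17 points (~2.1 s) prior,
  mean(v[f..f+2]) − mean(b) > 2·SD(b), with a 78-frame (~10 s) stability
  requirement and at least one confirming supra-threshold point after the
  rise; the sign-flipped criterion (`detect_negative()`) measures the
  false-positive rate.
- **Kinetics** — single-exponential decay fits
  A·e^(−(t−t₀)/τ) + c by Levenberg–Marquardt (`fit_decay()`), dwell times,
  onset-aligned average waveforms, and Beta-distribution summaries of decay
  constants (`fit_beta_decay()`).
- **Quantal decomposition** — constrained Gaussian mixtures over event
  amplitudes with component means at q, c·q (c ∈ [1.1, 1.6]) and exactly
  2q, SDs proportional to means (`fit_quantal_mixture()`), selected by a
  D'Agostino–Pearson normality gate plus χ² goodness of fit; the summed
  weight above 1q is the multivesicular fraction.
- **Overlap model** — the apparent amplitude of two quantal events whose
  onsets differ by a delay d under the 3-point sampling operator:
  f(t) = e^(−t/τ) + e^(−(t−d)/τ)·[t ≥ d] sampled at 0, Δt, 2Δt. At
  τ = 371 ms and Δt = 120 ms, d = 118 ms reads as 1.32 quanta — the origin
  of the ~1.3q mixture component (`apparent_amplitude()`, `find_delay()`).
- **Dual channel** — double-exponential photobleach linearization, local
  linear baseline correction, and one-to-one pre/post event coincidence
  matching within frame windows (`match_events()`).
- **Per-synapse statistics** — spontaneous rates (with large events counted
  as two vesicles), evoked fusion probability per stimulus, and the
  correlation between the two across synapses (`correlate_rates()`).
- **Synthetic data** — a ground-truth generator (`simulate_trace()`,
  `simulate_dual()`) emulating Poisson-timed quantal events, folimycin
  staircases, Tris-slowed decays, photobleaching and stimulus-locked evoked
  release, so the whole pipeline is testable without recordings.

## Worked example

Simulate twenty boutons for ten minutes at the spontaneous-release
conditions (0.5 events/bouton/min, q = 623 ± 122 a.u., τ = 371 ms), detect
events, and fit the first event's decay:

```r
library(synquant)

cfg <- trace_sim_config(duration = 600, spont_rate = 0.5, noise_sd = 62.3,
                        n_rois = 20, seed = 42)
sim <- simulate_trace(cfg)
events <- do.call(rbind, lapply(sim$traces, detect_events))
head(events[, c("roi_id", "onset_time", "amplitude", "dff")], 3)
#>   roi_id onset_time amplitude         dff
#> 1   roi1      80.88 381.22094 0.023266013
#> 2   roi1     117.84  91.94448 0.005613103
#> 3   roi1     171.72 430.41025 0.026249517

tr <- sim$traces[[1]]
fit_decay(tr, events[1, ])
#> <decay_fit> tau = 0.3697 s, A = 526.3, c = 1.641e+04 (n = 41)
```

The fitted τ of 0.37 s recovers the generative re-acidification constant;
amplitudes are the 3-point-average rise over the local baseline (a 623 a.u.
event reads ≈ 0.64× that after decay within the averaging window — the
attenuation is analytic and tested). `dff` is the rise relative to the
resting fluorescence (~2–4%).

Decompose an amplitude sample containing a multivesicular shoulder, holding
the calibrated quantal Gaussian fixed:

```r
fit <- fit_quantal_mixture(amps, q_init = 623, sigma_init = 122,
                           fix_quantal = TRUE)
fit
#> <quantal_mixture_fit> 2 component(s), q = 623.0, sigma_q = 122.0
#>   comp 1: mean 623.0 (x1.00), weight 0.840
#>   comp 2: mean 841.8 (x1.35), weight 0.160
#>   reduced chi2 = 1.053 (p = 0.393), normality p = 2.74e-18
multivesicular_fraction(fit)
#> [1] 0.16
```

(Here `amps` held 1200 amplitudes of which 17% were generated at 1.34q; the
fit recovers a 16% multivesicular fraction at c = 1.35.) The overlap model
explains such a component as two vesicles fusing ~118 ms apart:

```r
apparent_amplitude(delay = 0.118, tau = 0.371, sample_interval = 0.12)
#> [1] 1.3206
find_delay(1.32, tau = 0.371, sample_interval = 0.12)
#> [1] 0.1176
```

See the methods vignette (`vignettes/quantal-optical-analysis.Rmd`) for the
model assumptions, parameter meanings and the package's design decisions.

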