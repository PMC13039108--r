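# locusmotion

Single-locus chromatin motion analysis in R: from 2D time-lapse image
stacks (or track tables) to anomalous-diffusion parameters and population
statistics, with an exact fractional-Brownian-motion simulator standing in
for experimental data.

## What it is for

Live-cell tracking of a fluorescently labelled genomic locus produces a
diffraction-limited spot wandering across ~1000 frames at 100 ms intervals.
Biophysically, the question is how mobile that locus is, summarized by the
power law

```
MSD(Δt) ~ 2 n D Δt^α
```

with `n` the number of spatial dimensions, `D` the generalized diffusion
coefficient (µm²/s^α) and `α` the anomalous exponent (α < 1: subdiffusion,
the chromatin norm; α = 1: Brownian; α > 1: directed). The package is aimed
at microscopists and analysts who want this analysis chain reproducible and
testable end to end:

* **synthetic data** — exact fBM trajectories (circulant-embedding fGn),
  localization noise, drift, immobile fixed-cell analogs; rendering to
  16-bit TIFF stacks with a Gaussian PSF and camera noise
* **detection** — LoG / Hessian blob detectors with subpixel maxima
* **refinement** — bounded 9×9 2D Gaussian fitting (intensity 10–65000,
  sigma 0.36–3.60 px, greedy grid + Levenberg–Marquardt, fallback to the
  initializing coordinate when a fit fails)
* **tracking** — two-stage LAP linking (5 px link and gap-close radii,
  ≤ 3-frame gaps) and the 50-frame span filter
* **MSD analysis** — TA-MSD / ETA-MSD, power-law fits over lags
  1…max(round(0.10·T), 10), velocity autocorrelation, displacement
  Gaussianity, and a PCA minor-axis 1D fit as a drift control
* **statistics** — Kruskal–Wallis + Dunn pairwise comparisons,
  Hartigan's dip test (exact statistic, bootstrap p), 5–95% descriptives

## Worked example

One hundred subdiffusive tracks (α = 0.5, D = 0.01 µm²/s^0.5, 20 nm
localization error) at the default acquisition geometry, analysed exactly
as experimental tracks would be:

```r
library(locusmotion)

acq <- acquisition_params()          # 0.1 s frames, 0.067 um px, 1000 frames
trs <- simulate_tracks(100, sim_params(alpha_true = 0.5, D_true = 0.01,
                                       sigma_loc = 0.02, seed = 42), acq)

curve <- eta_msd(trs, acq, max_lag = fit_window(1000))
fit_power_law(curve, n_dims = 2, acq = acq, T_frames = 1000)
#> <motion_fit> alpha = 0.4869, D = 0.010444 um^2/s^alpha (2D, lags 1-100, R2 = 1.000)

fits <- fit_tracks(trs, acq)         # per-track alpha and D
summarize_groups(fits$alpha, rep("locus", nrow(fits)))
#>   group   n        p5       q25    median       q75       p95
#> 1 locus 100 0.4008031 0.4553184 0.4841713 0.5085007 0.5719046

round(velocity_autocorrelation(trs, acq, max_lag = 3)$vac, 3)
#> [1]  1.000 -0.315 -0.043 -0.024
```

The ensemble fit recovers the generative parameters (α 0.487 vs 0.5; D
0.0104 vs 0.01 µm²/s^0.5 — the small offsets come from the localization
noise floor and lag-window averaging), and the lag-1 velocity
autocorrelation is negative, the fBM anti-persistence signature (the pure
fBM value at α = 0.5 is 2^(α−1) − 1 ≈ −0.293; localization noise pushes it
lower). Testing the per-track D distribution for multimodality:

```r
dip_test(fits$D, n_boot = 500, seed = 1)
#> dip = 0.0322, p = 0.715      # no evidence of a slow/fast mixture
```

A rendered two-condition experiment (images, not just tracks) runs through
`run_pipeline()`; see `inst/extdata/demo-config.yaml` and the vignette in
`vignettes/chromatin-motion-analysis.Rmd` for the model, parameter and
design-choice documentation. A thin command-line front end over the same
functions lives at `inst/cli/locusmotion.R` (subcommands `simulate`,
`detect`, `track`, `analyze`, `stats`, `run`).

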