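---
title: "Quantifying chromatin locus mobility: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying chromatin locus mobility: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locusmotion)
```

## The measurement problem

A fluorescently labelled genomic locus imaged in a live nucleus appears as a
diffraction-limited spot wandering over a 2D time-lapse (typically 1000
frames at 100 ms intervals, 67 nm pixels). The quantity of interest is the
mobility of the locus, summarized by two parameters of an anomalous
diffusion law fitted to its mean squared displacement:

$$\mathrm{MSD}(\Delta t) \sim 2\,n\,D\,\Delta t^{\alpha},$$

where $n$ is the number of spatial dimensions (2 for image-plane tracks),
$D$ is the generalized diffusion coefficient in $\mu m^2/s^{\alpha}$, and
$\alpha$ is the anomalous exponent: $\alpha < 1$ is subdiffusive (typical of
chromatin, which behaves like a locus on a polymer in a viscoelastic
medium), $\alpha = 1$ is Brownian, $\alpha > 1$ indicates directed motion.
The modelling frame is fractional Brownian motion (fBM): Gaussian,
self-similar, with stationary and (for $\alpha<1$) negatively correlated
increments.

`locusmotion` implements the full chain from images (or track tables) to
population statistics, together with a synthetic-data generator that
produces trajectories and rendered image stacks with exactly the
statistical structure the analysis assumes. Every stage is therefore
testable without any experimental data.

## Trajectory model and generator

`simulate_fbm_track()` draws each axis independently as a cumulative sum of
fractional Gaussian noise (fGn) with Hurst exponent $H = \alpha/2$, scaled
so the noise-free per-axis displacement variance over a lag $\delta$ frames
is $2 D (\delta\,\mathrm{dt})^{\alpha}$. The fGn is sampled *exactly* by
circulant embedding of its covariance (the spectral eigenvalues of the fGn
embedding are provably non-negative; a jittered-Cholesky fallback guards
the numerical edge case and reports itself). Exactness matters: an
approximate generator would bias the very parameter-recovery checks the
package is validated with.

On top of the fBM core the generator adds, in order:

* **drift** — a constant velocity $v$ (um/s), mimicking slow substrate or
  nuclear motion;
* **localization error** — i.i.d. Gaussian noise of s.d. $\sigma_{loc}$
  per axis per frame. The default 0.02 um is a typical spinning-disk
  single-particle localization precision; the studies this pipeline is
  modelled on do not report theirs, so this value is a configurable
  stand-in, not a measured one.

Two useful closed forms follow from the model and anchor the tests:

* an immobile emitter ($D=0$) observed with localization noise has a flat
  2D MSD of $4\sigma_{loc}^2$ at every lag, and its fitted $\alpha$ is
  $\approx 0$ — the fixed-cell control;
* the normalized velocity autocorrelation of fBM at lag 1 frame is
  $2^{\alpha-1}-1$ ($\approx -0.293$ at $\alpha=0.5$; $-0.5$ in the
  pure-noise limit; $0$ for Brownian motion).

`render_stack()` converts tracks to pixel coordinates and draws each spot
as an isotropic 2D Gaussian (default $\sigma_{PSF} = 1.5$ px, amplitude 300
counts over a background of 100) with optional Poisson shot noise and
Gaussian readout noise (default s.d. 10), clipped to the 16-bit camera
range. Intensity is constant by default: photostable labels show little
bleaching over such acquisition windows, and bleaching kinetics are out of
scope (the QC slope in `track_qc()` is the guard).

What the generator does *not* emulate: non-Gaussian displacement mixtures
within one track, confinement, locus doublets (sister chromatids), focal
drift in z, and background structure from the nucleoplasm. Passing tests
therefore demonstrate correctness of the estimators under the model the
analysis assumes, not robustness to every feature of real nuclei.

## Detection and subpixel refinement

`detect_spots()` offers Laplacian-of-Gaussian and determinant-of-Hessian
blob detectors at the scale implied by the expected diameter
($\sigma = d/(2\sqrt2)$; 3.54 px for the default 10 px diameter), with
subpixel maxima by separable quadratic interpolation. The quality scales
are a documented dialect rather than a clone of any particular tracking
GUI: LoG quality is the scale-normalized response in counts (default
threshold 25 — an amplitude-300 spot scores about 75, pure readout noise
of s.d. 10 about 1), while the Hessian quality is normalized per frame to
[0, 1] (default 0.7), which makes it a relative detector; false-positive
control on empty frames is the LoG detector's job.

`refine_spot()` implements bounded 2D Gaussian fitting on a 9×9 patch:
amplitude within [10, 65000] counts, $\sigma_{PSF}$ within [0.36, 3.60] px.
The two-stage scheme resolves what a "greedy search with steps 1.0 and
0.040" leaves open: stage one scans the $\sigma$ grid at the configured
step, using the closed-form least-squares amplitude (snapped to the
intensity step) against a constant background estimated as the median of
the patch's 32 border pixels; stage two runs bounded Levenberg–Marquardt
over $(x, y, \sigma, A, b)$. A fit **succeeds** only if it converges with
all parameters strictly inside bounds and a centre displacement below 2 px
from the initialization (preventing latch-on to a neighbouring spot);
otherwise the initializing coordinate is kept verbatim and flagged
(`source = "fallback-initial"`), so every frame yields exactly one
localization. Whether the background should float during the greedy stage
is not specified anywhere we know of; fixing it in stage one and freeing it
in stage two is this package's choice and is recorded here so alternatives
can be compared.

On noiseless fixtures the refinement is exact to the optimizer tolerance
(< 0.01 px); at amplitude 300 over background 100 with readout s.d. 10 the
RMSE is below 0.1 px (about 0.025 px in our fixtures, i.e. ~1.7 nm at
67 nm pixels).

## Linking and track filtering

`link_spots()` is a two-stage linear-assignment (LAP) tracker:
frame-to-frame links minimize summed squared distances (forbidden beyond 5
px by default), then segment ends and starts are matched for gap closing
across 2–4 frame steps (a maximum of 3 missing frames) within 5 px. The
alternative (no-link) cost is $(1.05 \cdot d_{max})^2$, the standard LAP
convention; since any allowed link costs at most $d_{max}^2 < 2(1.05\,
d_{max})^2$, links within range are always preferred to a birth/death
pair. The assignment solver is an $O(n^3)$ Hungarian implementation with
potentials, validated against exhaustive permutation search. Splitting and
merging are disabled: the intended use tracks one locus per region of
interest.

`filter_tracks()` keeps tracks whose **span** — last minus first detected
frame plus one, gaps included — is at least 50 frames. Span, not detection
count, is used deliberately: a track bridged across gaps still covers the
time interval its span states; the choice matters only for gapped tracks
and is flagged here because the 50-frame rule could also be read as a
detection count.

## MSD analysis

For a track observed at $T$ discrete times,

$$\mathrm{TA\text{-}MSD}(\delta) = \frac{1}{T-\delta}
\sum_{i=1}^{T-\delta} \left| r(t_i) - r(t_i+\delta) \right|^2,
\qquad
\mathrm{ETA\text{-}MSD}(\delta) = \frac{1}{N}\sum_{i=1}^{N}
\mathrm{TA\text{-}MSD}_i(\delta).$$

Numerical choices, each recorded in the outputs:

* **Gaps**: the time average runs over realized pairs only, with the
  realized pair count as divisor (unbiased under missingness at random);
  pair counts are stored per lag.
* **Ensemble averaging**: the unweighted mean over tracks that possess the
  lag, per the ETA-MSD formula — not pair-count weighted; the number of
  contributing tracks is recorded per lag.
* **Fit window**: lags 1 to $\max(\mathrm{round}(0.10\,T),\,10)$ frames —
  "10% of the maximum track length or at least 10 frames" read as the
  maximum of the two — capped at the available lags.
* **Fit space**: ordinary least squares of $\log \mathrm{MSD}$ on
  $\log \Delta t$ (seconds), unweighted; $\alpha$ is the slope and
  $D = e^{\mathrm{intercept}}/(2n)$. Log-log OLS is the field's standard;
  the choice is stored in each `motion_fit` so alternatives remain
  comparable. Non-positive MSD values in the window are dropped and
  counted; fewer than three usable lags is an error.
* **Units**: trajectories live in um and lags in seconds, so $D$ is in
  $\mu m^2/s^{\alpha}$; pixel units exist only at the image boundary
  (67 nm default). No localization-noise correction is applied to the MSD
  — none is standard in this assay — so small-$\alpha$, small-$D$ regimes
  should be read as noise-floor-limited rather than literal.

`pca_1d_diffusion()` is the drift control: the track's coordinates are
projected onto the principal axis of **lowest** variance (perpendicular to
the longest axis, which is the direction a slowly moving substrate
inflates), and the TA-MSD power law is fitted in one dimension. Linear
drift lives almost entirely along the major axis, so the minor-axis
exponent recovers the generative $\alpha$ while the naive 2D fit is biased
toward ballistic. A perfectly collinear track has no minor-axis signal and
is rejected (relative eigenvalue ratio below $10^{-6}$).

## Population statistics

Per-track $(\alpha, D)$ values are compared across conditions with the
tie-corrected Kruskal–Wallis omnibus test (base R's `kruskal.test`)
followed by Dunn's pairwise $z$ comparisons on mean ranks with the shared
tie-corrected variance. The family-wise adjustment for the Dunn p-values
defaults to Holm — the adjustment used in the motivating analyses is not
public, so it is configurable (`"holm"`, `"bonferroni"`, `"none"`) and
recorded in the output object. Fully tied inputs short-circuit to
$H = 0$, $p = 1$ (ties maximally corrected).

Multimodality of the per-track parameter distributions is assessed with
Hartigan's dip statistic: the smallest sup-norm distance between the
empirical CDF and any unimodal CDF. `dip_stat()` evaluates it **exactly**
through the excess-mass identity — the dip equals half the maximum over
the density level $\lambda$ of $E_2(\lambda) - E_1(\lambda)$, the
two-interval minus one-interval excess masses. Both curves are piecewise
linear and convex in $\lambda$, and their difference can only turn
downward at a vertex of the one-interval envelope, so scanning those
$O(n)$ breakpoints (from the convex hull of interval width/mass pairs)
finds the global maximum exactly. This route was chosen over the classical
iterative minorant/majorant algorithm because it is easier to verify: the
implementation agrees to $10^{-13}$ with an independent brute-force
enumeration, and reproduces the known closed cases ($1/8$ for four equally
spaced points, $1/4$ in the two-cluster limit, $1/(2n)$ for
convexity-compatible samples). P-values come from a seeded bootstrap of
Uniform(0,1) samples at matched $n$ — the standard calibration null for
the dip — rather than from interpolation tables; `dip_null()` lets many
tests at one sample size share a single null table. Note that for data
from lighter-tailed unimodal laws (e.g. Gaussian) the uniform null is
conservative; that is a property of the dip test itself, not of this
implementation.

Descriptive summaries report median, quartiles and 5th/95th percentiles
(type-7 linear interpolation), matching boxplots drawn with IQR boxes and
5–95% whiskers.

## The orchestrated pipeline

`run_pipeline()` chains simulate → render → detect → link → filter →
refine → fit (2D and PCA-1D) → group statistics, one locus per rendered
region of interest, writing per-stage logs with the counts a QC reader
greps for (candidates, filter survivors, fit successes), the resolved
configuration, CSV/XML track tables, and a manifest with MD5 checksums.
Identical configuration and seed reproduce identical tables and checksums.
Configurations are YAML (`read_run_config()`), with conditions expressed
as overrides of the base simulation parameters; a demo configuration with
a 2× faster condition ships in `inst/extdata/demo-config.yaml`.

## Validation scale and limitations

The test suite validates parameter recovery at 200 tracks × 1000 frames
per exponent ($\alpha \in \{0.3, 0.5, 1.0\}$, median $\alpha$ within
±0.05, median $D$ within ±10%), the fixed-spot control at 50 tracks ×
1000 frames, drift cancellation at 100 tracks × 500 frames, statistical
calibration at 1000 replicates (acceptance band 3.5–6.5% at nominal 5%),
and the rendered end-to-end experiment at 2 conditions × 12 tracks × 120
frames on 48×48 images — sizes chosen so the whole suite runs on a laptop
in minutes while keeping Monte-Carlo error well inside the asserted
tolerances.

Known limitations: detector quality scales are a dialect (absolute
thresholds from other software do not transfer exactly); no 3D or
astigmatic PSF model; no doublet classification beyond a
one-spot-per-ROI assumption; no confinement or polymer-model fitting; no
hidden-state segmentation — the statistics operate on population
distributions of per-track parameters, which is exactly the scope of the
motivating assay.
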