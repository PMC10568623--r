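---
title: "strokenet: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{strokenet: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements: the
signal models, the estimators, every tunable parameter that matters, what the
synthetic-data generator does and does not emulate, and the design choices
made where the underlying methodology left the design genuinely open.

# The pipeline

`strokenet` predicts a continuous standardized cognitive score (3-month MoCA)
from 19-channel resting EEG in acute ischemic stroke. The chain is

> filter → re-reference → epoch/reject → Welch spectra → sLORETA sources →
> imaginary coherence → proportional thresholding → graph attributes →
> laterality classification → group-wise feature selection → LOO regression.

## Sensor-level preprocessing

* **Band-pass 1–45.5 Hz, notch at the mains frequency.** Filtering is done in
  the frequency domain by multiplying each channel's FFT with a real,
  non-negative 4th-order Butterworth magnitude response (plus a narrow
  Gaussian band-stop for the notch). A real multiplicative response has
  exactly zero phase, so no time-domain `filtfilt` machinery is needed, and
  stop-band attenuation exceeds 20 dB well inside the stop bands. The notch
  defaults to 60 Hz (`notch = 50` available) because the mains frequency of
  the original recordings is not documented.
* **Common average reference (CAR).** Subtracting the instantaneous channel
  mean; linear and channel-symmetric, so it commutes with filtering (a tested
  invariant).
* **Epoching: 4 s windows, 50% overlap.** 4 s gives 0.25 Hz native resolution,
  comfortably resolving the 1 Hz lower edge of the delta band. The artifact
  pass drops epochs whose peak amplitude exceeds 100 µV or whose per-channel
  variance exceeds 5× that channel's median epoch variance. These two rules
  are a documented, deterministic stand-in for the proprietary cleaning chain
  (artifact-subspace reconstruction plus ICA) used with clinical recordings;
  an externally computed ICA cleanup can be applied to the recording before
  epoching. If every epoch is rejected the pipeline stops with an explicit
  "no analyzable data" error rather than proceeding silently.

## Spectral features

Welch PSD with a Hann window, 2 s segments (500 samples at 250 Hz), 50%
segment overlap: 0.5 Hz resolution puts a frequency bin exactly on every band
edge. Bands are half-open `[lo, hi)` so shared edges are counted once. The
eight bands are delta (1–4), theta (4–8), alpha1 (8–10), alpha2 (10–12),
beta1 (12–15), beta2 (15–20), beta3 (20–30), gamma (30–45 Hz); relative power
is each band's share of the 1–45 Hz total, so relative powers sum to 1 per
channel to numerical precision. The ratio features use composite bands:
TAR = theta/(alpha1+alpha2), TBR = theta/(beta1+beta2+beta3),
TBR2 = theta/beta2, DAR = delta/(alpha1+alpha2) — the conventional reading of
"theta/alpha" and "theta/beta". Zero denominators yield flagged missing
values, never infinities.

## Source model

The inverse solution is sLORETA with fixed (scalar) source orientations: the
minimum-norm kernel `K = Gᵀ(GGᵀ + αI)⁻¹` standardized per source by
`sqrt(diag(KG))`. For a single active source and noiseless data the
standardized power peaks exactly at the true source — this follows from the
Cauchy–Schwarz inequality applied to the resolution matrix, and the test
suite verifies it for 100 random leadfields. The default regularization is
`α = 0.05 × mean eigenvalue of GGᵀ`, a scale-free choice used when no noise
covariance is available. Sources are aggregated to the 68 Desikan–Killiany
ROIs by the arithmetic mean of member sources (a first-principal-component
option exists; the mean is deterministic and sign-stable under the smooth
synthetic leadfields used for testing). The packaged ROI table encodes the
numbering convention: even ROI numbers are left-hemisphere, odd numbers
right-hemisphere, ROIs 1–20 are frontal, and lobes are
frontal/temporal/parietal/occipital/isthmus/other. The exact within-lobe
ordering of region names is the package's own convention (the original
supplementary mapping is not public), which matters only for interpreting
individual ROI numbers, not for any computed metric.

## Connectivity and networks

The cross-spectral density between ROI time courses uses the same Welch
segmentation as the PSD. Imaginary coherence for band *B* between ROIs *x*
and *y* is

$$\mathrm{iCOH}_B(x,y) \;=\; \Bigl|\; \tfrac{1}{|B|}\sum_{f \in B}
\mathrm{Im}\, \frac{S_{xy}(f)}{\sqrt{S_{xx}(f)\,S_{yy}(f)}} \Bigr|.$$

Two aggregation decisions deserve comment:

* **Magnitude.** The sign of the imaginary part only encodes which signal
  leads; proportional thresholding needs a one-sided ordering, so the
  magnitude is the edge weight.
* **Signed mean across bins, then magnitude.** Averaging `|Im|` per bin first
  looks natural but carries a half-normal null bias
  (`E|N(0,σ)| = σ·sqrt(2/π)`) large enough at 1–2 minutes of data to make
  truly uncoupled pairs look weakly connected. Averaging the signed values
  first lets estimation noise cancel across bins while a genuine lagged
  interaction — whose imaginary part has constant sign throughout the band —
  is unaffected. The volume-conduction null (identical or zero-lag-mixed
  signals give iCOH < 0.05 with two minutes of data) holds with this
  estimator and is enforced by tests.

Each band's 68×68 matrix is thresholded proportionally: the
`floor(0.25 × 2278) = 569` largest upper-triangle entries are retained
(ties broken deterministically by index), fixing the density at 25% for every
subject and band; thresholding composes idempotently. Metrics are computed on
the weighted graph by default (edge weight = iCOH, path length = 1/weight;
binary mode available):

* **global efficiency** — mean of 1/distance over ordered pairs (1/∞ = 0);
* **characteristic path length** — mean distance over *connected* pairs, with
  a disconnection flag (25%-density graphs can fragment; exclusion is the
  common convention);
* **clustering coefficient** — binary triangle closure, or the Onnela
  geometric-mean variant for weighted graphs, per node and averaged;
* **modularity** — best quality over 10 seeded Louvain restarts with permuted
  vertex order (the algorithm is order-sensitive; seeding makes the best-of-k
  deterministic);
* **nodal efficiency** — per-node mean of 1/distance to all others.

All distance/clustering/modularity values are cross-checked against
brute-force Floyd–Warshall, triangle-count and direct-Q oracles on hundreds
of random graphs. Per band this yields 140 features (3 global + modularity +
68 nodal clustering + 68 nodal efficiency), 1120 across the 8 bands, with
names like `theta_global_efficiency` and `alpha2_clustering_ROI3` that parse
back to band/metric/ROI/hemisphere/lobe.

## The two-stage prediction model

**Stage 1 — lesion laterality.** Slow waves predominate near the infarct, so
lesion side is decodable from spectral features. The classifier is a seeded
bagged ensemble of depth-limited CART trees (implemented in-package;
variance-reduction splits, per-node feature subsampling) evaluated by
leave-one-out on the unilateral subjects; bilateral subjects are then
assigned to a side by the trained model, so the cohort partitions into
exactly two groups.

**Stage 2 — group-wise outcome regression.** Within each laterality group,
using network features only: (i) keep features with Pearson |r| > 0.3 against
the outcome (zero-variance features are excluded and logged); (ii) rank the
survivors by split-gain importance from a seeded bagged-tree regression,
normalized to sum to one; (iii) select the top 20; (iv) fit Ridge, Lasso,
ElasticNet, SVR and AdaBoost.R2 by leave-one-out, reporting one pooled
`R² = 1 − SS_res/SS_tot` per model (a per-fold R² is undefined for single
held-out points; LOO R² may be negative and is always ≤ 1). Penalized
regressions tune λ on a small inner cross-validated grid *within each
training fold*; SVR is a smoothed ε-insensitive kernel regression fitted by
L-BFGS; AdaBoost.R2 uses linear loss over shallow trees with weighted-median
prediction. The selection summary tabulates the selected features by
frequency band and by lobe with counts and summed normalized importance
(global, non-nodal attributes have no lobe and fall in "others").

**Selection timing.** The published flow runs feature selection once on the
whole group before cross-validation ("paper" mode, the default). This leaks
the held-out outcome into the *selection* (not the fit): on null cohorts with
1120 candidate features at n = 100, paper-mode selection inflates LOO R² to
roughly 0.15 even though no real signal exists. The package therefore also
provides a "strict" mode that re-runs the entire selection inside every LOO
training fold and is leakage-free by construction; the acceptance null check
is performed with an outcome-independent feature set, which isolates the
regression stage itself (the fitted models never see the held-out outcome —
a perturbation test verifies each subject's LOO prediction is bit-identical
under changes to that subject's outcome).

**Composite sensitivity search.** Subsets combining 3–5 of the top-5 features
with members of the next 15 (≤ 10 features total) are enumerated — or, above
the 9,000-model budget, sampled without replacement with a seeded RNG — and
each is refitted by LOO. The enumeration rule is configurable because the
constraint set admits many more subsets than the published "close to 9,000";
an exact-count helper (`count_composite_models()`) makes the chosen rule
auditable.

# The synthetic cohort: what it emulates, and what a green test means

No clinical recordings are distributable, so the generator builds cohorts
with planted, recoverable ground truth. All randomness flows from one master
seed through a documented splitter (`derive_seeds()`), making every cohort
bit-reproducible.

* **Oscillators** are band-pass-filtered Gaussian noise, not sinusoids:
  Welch-type estimators need stochastic signals for coherence below 1 and
  realistic spectra. Coupled ROI pairs share a narrowband carrier; the second
  ROI receives a copy rotated by the specified phase lag (via the analytic
  signal), so a π/2 lag yields iCOH near 1 and a zero lag yields high real
  coherence but zero imaginary coherence — the volume-conduction null that
  motivates the connectivity measure.
* **Lesion laterality** is a delta+theta source-amplitude multiplier
  (default 2.0) on the lesioned hemisphere's ROIs, projected through a
  hemisphere-structured smooth random leadfield (same-side gains dominate);
  bilateral subjects receive the excess on both sides. The default lesion-side
  distribution (40/36/24% left/right/bilateral) mirrors a typical acute-stroke
  cohort in which about a quarter of patients have bilateral lesions.
* **Outcome.** In feature mode the standardized score is a linear combination
  of three theta-band network features (global efficiency and two nodal
  attributes, equal unit weights) plus Gaussian noise scaled so the planted
  signal explains a chosen fraction of variance (default 0.8), then mapped to
  a mean-50, SD-10 scale. The score scale is deliberately generic: the
  norm-standardization tables behind clinical MoCA standardized scores are
  out of scope. In EEG mode the per-subject theta coupling strengths — the
  latent drivers of the theta network attributes — generate the outcome,
  because exact network-feature values are only defined after the full
  estimation chain.
* **Not emulated:** real head anatomy or BEM forward models, electrode
  digitization, eye-blink/EMG artifacts needing subspace cleanup, non-Gaussian
  score distributions, and correlations between feature families. A green
  end-to-end test therefore establishes that the estimators and the selection
  + validation machinery recover planted effects of realistic size at clinical
  sample sizes — not that the clinical effect sizes themselves are correct.

# Numerical choices and degenerate inputs

* Band intervals half-open; ties in proportional thresholding broken by
  (row, column) index; Louvain restarts seeded; all ensembles seeded.
* Zero PSD at a band bin flags the connectivity entry as missing; zero-variance
  features are excluded from correlation filtering with a log entry; an
  all-zero connectivity matrix yields an empty network with a warning;
  an empty post-filter feature set falls back to the mean predictor with a
  warning; rank-deficient leadfields are rejected at construction, and α = 0
  inversion of a singular sensor Gram matrix raises an error advising α > 0.
* `glmnet` requires two predictor columns; single-feature fits are padded
  with a zero column (invisible to the result).
* EDF export quantizes to 16 bits over the recording's physical range
  (relative error ≤ 2⁻¹⁵ of the range per sample).

# Runtime scaling in tests

The acceptance checks run the stated cohort sizes (n = 100 recovery, n = 60
laterality, 20-seed null sweeps) but shorten EEG-mode recordings to 15 s for
the laterality sweeps; at 2× slow-wave asymmetry the hemispheric power
contrast is far above the detection floor at that length, and the null sweeps
are null at any length. Everything else runs at the stated sizes.

# Known limitations

* The sLORETA operator uses an identity noise covariance and scalar sources;
  depth weighting and free orientations are not implemented.
* Sensor-space connectivity, directed measures (Granger, PDC) and phase-lag
  index variants are out of scope.
* The laterality classifier and importance ranker are bagged CART ensembles;
  they are deterministic given the seed but, like all tree importances,
  can dilute credit among strongly correlated features.
* Real-data headline numbers from the motivating clinical study are not
  reproducible here (the cohort is not deposited); no test asserts them.
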