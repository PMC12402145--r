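---
title: "Timestamping amyloid plaques: models, parameters and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Timestamping amyloid plaques: models, parameters and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plaquetime)
```

`plaquetime` turns ¹⁵N isotopologue signatures of Aβ1-42 in MALDI-MSI
spectra into a per-plaque age proxy (the *nitrogen index*) and links that
proxy to single-plaque gene expression, amyloid structural maturity and
peri-plaque marker profiles. This vignette documents the models behind each
step, the tunable parameters with their defaults and units, what the
synthetic-data generator does and does not emulate, and the numerical
choices a maintainer should know about.

## 1. Isotopologue model

A peptide's isotopologue distribution is the convolution of independent
per-element isotope distributions. For Aβ1-42 (C203 H311 N55 O60 S1,
monoisotopic [M+H]⁺ = 4512.28) under ¹⁵N labeling, the nitrogen channel is
Binomial(55, q) where q is the probability that a nitrogen is ¹⁵N (natural
abundance 0.00364); C, H, O and S keep natural abundances. The engine
convolves per-element distributions with binary exponentiation, tracking
per-bin probability and probability-weighted mass so each nominal-mass bin
carries its exact conditional mean mass.

**Binning.** ¹³C and ¹⁵N substitutions differ by 6.3 mDa — unresolvable at
m/Δm = 15000 — so fine structure is aggregated into nominal-mass bins about
1 Da apart, each centroided by abundance. **Pruning** drops bins below
1e-10 (configurable) before renormalization; abundances then sum to 1
within 1e-9. Two closed forms anchor the tests: the centroid shift
Δm = 55·(q − 0.00364)·0.99703 Da, and bin-by-bin agreement (< 1e-10) with a
brute-force multinomial enumeration on small molecules.

## 2. Spectral engine

### ALS baseline and the lambda convention

The baseline minimizes Σ w_i (y_i − z_i)² + λ Σ (Δ²z_i)² with asymmetric
weights w = p (default 0.025) above the baseline and 1 − p below, iterated
(maxit = 100) until no weight flips. `lambda` is a **log10 exponent**
(effective penalty 10^λ): single-digit literal penalties make the smoother
so flexible that the baseline tracks the analyte peak itself (on our LP
grid a literal λ = 5 leaves ~0.5% of the peak after correction and every
fit fails the R² gate), whereas 10³–10⁸ is the conventional ALS range. The
penalty's effect scales with sampling density (roughly as the fourth power
of points per Da), which is why the two modes default differently:
λ = 7 for LP (0.05 Da grid, ~5 Da wide peak) and λ = 5 for RP (0.01 Da
grid, 0.3 Da peaks). Stiffer LP baselines (λ = 8–9) reduce the systematic
described below but track curved chemical backgrounds less well.

Two properties of ALS worth knowing. First, with noise the equilibrium
baseline sits ~1.4 noise-SD *below* the true background (the p = 0.025
asymmetry balances there); this cancels in baseline-corrected areas and
shifts FWHM negligibly. Second, under any finite-λ baseline some peak mass
is absorbed: at defaults the LP FWHM is systematically ~10% narrow. Because
the index is used as a correlation axis (rank information), this
monotonicity-preserving compression is harmless; it is why the pipeline
does not claim absolute enrichment quantification in LP mode.

### LP index

Local maxima are intensities above both immediate neighbors (plateaus count
once, at their lowest index); the main peak is the most intense maximum
(ties to lowest m/z); the fitting window extends ±3 instrument FWHM
(instrument FWHM = m/resolving power; m/Δm = 1000 at m/z 4515) around the
apex. The split Gaussian A·exp(−(x−c)²/2σ²_{L,R}) is fitted by bounded
Levenberg–Marquardt (start values from the data; A ≤ 2·max, c inside the
window, σ ≤ window width), and the index is the analytic
FWHM = √(2 ln 2)(σ_L + σ_R). QC passes when the fit converged with
R² > 0.90. At SNR 20 the fit recovers planted parameters with ~2% median
error; noiseless inputs are recovered to solver tolerance (≤ 1e-3).

### RP index

The isotopologue ladder is anchored at the predicted monoisotopic m/z of
the target composition, snapped to the nearest apex within ±0.3 Da, then
walked in +1.00335 Da steps with the same snap. Each peak's area is the
trapezoid integral of the corrected trace between the first samples at or
below zero flanking the apex (the local intersections with the fitted
baseline). The index is area(4th)/area(3rd), **counting 1-based from the
monoisotopic bin** — the convention is configurable (`peak_i`, `peak_j`)
since counting could also start from the first detectable peak in noisy
data. Against exact theory the measured ratio is within ~1% over
q = 0–0.25 noiseless. The ratio's informative range ends near q ≈ 0.3:
beyond that the 3rd/4th isotopologue abundances fall below any realistic
dynamic range (at q = 0.4 they are ~1e-10).

## 3. Synthetic-data generator

The generator is the package's ground-truth instrument; all recovery claims
are claims about these study conditions.

**Labeling kinetics.** Body-pool enrichment rises as
e_max(1 − exp(−k_in t′)) during the pulse (6–10 months) and decays as
exp(−k_out t″) during the chase, floored at natural abundance. Defaults
e_max = 0.25, k_in = 3/month, k_out = 1/month are the generator's own
model — no kinetic equations or plateau value are established for this
paradigm — chosen so the pool saturates within the pulse and washes out
over a few months. Consequences worth stating plainly: in the **pulse-only
design** (cull at 10 months, plaque onset 9 months) nearly all plaques form
after the pool saturates, so between-plaque enrichment contrast is ~1e-4 —
sign-level truths (center < periphery) hold but no estimator could recover
age ranks from spectra; recovery experiments therefore use the
**pulse-chase design**, where mean enrichments span ~0.004–0.19.

**Deposition.** A plaque born at time b deposits material at a rate
declining exponentially with its own age (`deposition_decay`, default
1/month): plaque growth saturates, and the growth-ring picture puts the
first-deposited material at the core. A constant-rate alternative
(`deposition_decay = 0`) makes old plaques' content overwhelmingly
chase-period material and the FWHM nearly age-blind — a useful negative
control but not a realistic model of saturating growth. The plaque pattern
is the deposition-weighted mixture of patterns at the enrichment prevailing
at each deposition time (15 quadrature nodes); "center" sub-ROIs weight the
earliest third of the deposition interval, "periphery" the latest third
(a configurable simplification of a continuous radial gradient).

**Rendering.** Mixtures are convolved with a Gaussian instrument response
(FWHM = m/resolving power at the mode's reference m/z) on grids mirroring
TOF digitization (LP 0.05 Da, RP 0.01 Da), plus a smooth exponential
chemical background and white noise; background and noise amplitudes both
scale as 1/SNR, so `snr = Inf` is the clean trace. SNR is max signal over
noise SD; cohort defaults use SNR 20.

**Expression.** Planted genes carry a latent Gaussian with Pearson ±ρ
(default 0.8) to plaque age, mapped through a log link (scale 0.5/SD) to
negative-binomial counts (size 20, base mean 200) with lognormal AOI size
factors (SD 0.1). Nulls are independent. What passing tests show: at
n = 18 AOIs the pipeline detects ρ = 0.8 genes against *true age* with
sensitivity ≥ 0.9 and holds the null false-positive rate at ~0.05.
What they do not show: sensitivity against the *measured* index is lower
(the index is a noisy, nonlinear readout of age — the stage-3 analysis
script reports both numbers), and real GeoMx counts have gene–gene
correlation structure, batch effects and dropout the generator omits.

**Hyperspectral and IHC.** LCO references are Gaussians on a 32-channel
450–700 nm grid peaking at 500 nm (q-FTAA, SD 25 nm) and 580 nm (h-FTAA,
SD 30 nm); measured references can be substituted via CSV. Plaques are
radial blobs with class-determined q/h levels; the core q-fraction rises
with age, so older cores carry higher 500/580 ratios by construction. IHC
channels are painted piecewise-constant on exactly the Euclidean
distance-transform shells the analysis measures, making noiseless profile
recovery exact by design — real peri-plaque gradients are continuous, so
ring means on real data estimate averages, not plateaus.

## 4. Downstream analyses: choices and conventions

- **Quantile normalization** uses limma's engine with ties averaged. With
  ties present, "identical sorted columns" and "ties get the mean of their
  spanned ranks" cannot both hold exactly — on continuous data the
  normalization is exactly idempotent with identical sorted columns; on
  counts it is approximate (a property of mean-of-ties QN generally).
- **Sign convention.** Under pulse-chase labeling a higher index means an
  older plaque; under pulse-only the label marks recent deposition, so the
  age axis is inverted before gene correlations are reported. Flipping the
  design negates every r exactly.
- **Pearson p-values** use the exact t transform with n − 2 df; a
  permutation option exists for very small n. AOIs failing the R² gate are
  excluded before correlation, and exclusion precedes normalization.
- **ORA** is a one-sided Fisher exact test per gene set against the full
  measured background, BH-corrected across sets; gene sets arrive as user
  GMT files (no term database is bundled — term lists are
  database-version-dependent).
- **Low-count filter**: genes with geometric-mean count < 1 are dropped
  (configurable floor); probe-level vendor QC is out of scope, with only
  the iterative two-sided Grubbs screen (α = 0.01) implemented.
- **Unmixing** solves two-component non-negative least squares per pixel in
  closed form (unconstrained 2×2 solution if inside the cone, else the
  better single-component fit). Positivity thresholds for q+/h+ have no
  established values; they are explicit arguments, with Otsu on pooled
  object means as a data-driven option. The combination h−q+ contradicts
  the maturation ordering and is flagged `anomalous` rather than assigned.
- **500/580 ratio** uses the channel nearest each wavelength (discrete
  detector bins; no interpolation). For z-stacks, the plane maximizing the
  in-mask 500/580 ratio is selected.
- **Rings** are exact Euclidean-distance-transform shells
  (Felzenszwalb–Huttenlocher two-pass, pixel-center sampling) at 10 µm
  increments to 30 µm; pixel size must be supplied. Overlap removal is
  symmetric and pixel-level: a pixel claimed by two plaques' ring systems
  is excluded from both — the strictest reading of removing contested
  area. Aggregation averages plaques within (class, image), then images
  within (class, animal), with an optional >2 SD within-group exclusion.
- **Power analysis** computes exact noncentral-t power and searches n
  upward from 2. The one-sample one-sided family is the default because it
  is the unique standard configuration reproducing the reference minima
  (d = 2.5 → n = 3, d = 1.5 → n = 5 at α = 0.05, power 0.8); other
  families are available via `test=`.

## 5. Problem sizes and numerical notes

Recovery experiments use 20-plaque cohorts at SNR 20 (50 seeds for the
headline Spearman ≥ 0.9 claim), 18-AOI expression cohorts (200 seeds for
the null calibration), 160² hyperspectral images and 9-plaque class
cohorts — sizes chosen to mirror the study's per-animal scale while keeping
a full run in minutes on one core. Degenerate inputs are handled
explicitly: zero-variance genes and constant covariates are flagged rather
than propagated as NaN; empty rings are excluded from aggregation;
`select_main_peak` distinguishes "no peak" from fit failure; Grubbs guards
zero SD; the RP ladder reports which isotopologue was unreachable.
Simulators are pure functions of (parameters, seed) and restore the
caller's RNG state.

## 6. Known limitations

- The LP FWHM is a *relative* age proxy: baseline-induced compression
  (§2) and the nonlinear enrichment–age map mean absolute Δm is better
  read from the RP centroid/ratio.
- Modified or truncated Aβ species and charge states beyond the formula
  are out of scope (the model system predominantly produces intact
  Aβ1-42).
- No pixel-level MSI reconstruction, mass recalibration or cross-modality
  image registration: plaque identity across modalities is a user-supplied
  mapping, as in manual overlay practice.
- The synthetic generator's kinetic constants are plausible but not
  measured; conclusions about *real* recovery rates at a given SNR
  transfer only insofar as those constants do.
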