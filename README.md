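# plaquetime

Amyloid plaques accumulate over months to years, but a tissue section shows
them all at a single moment. Metabolic ¹⁵N labeling (iSILK) breaks that
degeneracy: mice fed a ¹⁵N diet during a defined pulse (6–10 months of age)
deposit isotopically heavy Aβ1-42 while the label is in the body pool, so the
isotope content of each plaque encodes *when* its material was laid down.
`plaquetime` implements the computational side of that experiment for
analysts working with MALDI mass-spectrometry imaging (MSI), GeoMx-style
single-plaque transcriptomics, hyperspectral LCO (q-FTAA / h-FTAA) amyloid
microscopy, and radial immunohistochemistry profiling — together with a
seeded synthetic-data generator that provides ground truth for every
modality.

## The nitrogen index

Aβ1-42 (`DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVVIA`) carries 55 nitrogen
atoms; its singly protonated monoisotopic ion sits at m/z 4512.3. If each
nitrogen is ¹⁵N with probability *q*, the isotopologue envelope is the
convolution of a Binomial(55, *q*) nitrogen channel with the natural C/H/O/S
isotope pattern, so the envelope centroid shifts by

    Δm = 55 · (q − 0.00364) · 0.99703 Da

and its variance grows with 55·q(1−q). The package computes these patterns
exactly (aggregated into nominal-mass bins) and reads the enrichment back
out of measured spectra as a **nitrogen index**, in two instrument modes:

- **LP (linear positive, m/Δm = 1000).** The envelope is one broad peak.
  Pipeline: asymmetric-least-squares (ALS) baseline → local-maxima peak
  picking → symmetric fitting window → bounded nonlinear least squares fit
  of a split Gaussian `A·exp(−(x−c)²/2σ²_{L,R})` → index = FWHM
  = √(2 ln 2)·(σ_L + σ_R), with an R² > 0.90 quality gate.
- **RP (reflector positive, m/Δm = 15000).** Isotopologues are resolved;
  index = area(4th peak) / area(3rd peak), each area integrated by
  trapezoids between the peak's intersections with the fitted baseline,
  compared against the exact theoretical ratio.

Downstream, the index is the plaque-age axis for gene-wise Pearson
correlations (quantile-normalized counts, non-FDR p < 0.05 volcano split,
one-sided Fisher ORA with Benjamini–Hochberg control), for LCO maturity
ratios (non-negative linear unmixing of 32-channel emission, 500/580 nm
core ratios, Aβ+h+q+ / Aβ+h+q− / Aβ+h−q− typing), and for
distance-transform ring profiles of LAMP1/HOMER1-like markers (10 µm shells
to 30 µm, symmetric overlap removal, class × image × animal aggregation).

## Worked example

```r
library(plaquetime)

design <- labeling_design("pulse_chase")          # pulse 6-10 mo, cull 18 mo
cohort <- simulate_cohort(20, design, mode = "LP", snr = 20, seed = 1)
idx <- lapply(cohort$spectra, nitrogen_index_lp)
ok <- sapply(idx, `[[`, "qc_pass")
cor(cohort$truth$age[ok], sapply(idx, `[[`, "value")[ok], method = "spearman")
#> [1] 0.9108696
```

The cohort's 20 plaques are born uniformly between pathology onset
(9 months) and cull; their true mean enrichments span 0.0037–0.19 and the
fitted FWHM recovers their age ranking (Spearman ρ ≈ 0.91 at SNR 20; median
0.895 over ten cohorts in `analysis/02_nitrogen_index.R`). In reflector
mode the measured 4th/3rd area ratio reproduces the exact pattern ratio to
within 1% across q = 0–0.25 (noiseless).

The numbered scripts under `analysis/` run the full study workflow —
`01_simulate_cohorts.R` (both labeling designs plus center/periphery
contrasts), `02_nitrogen_index.R`, `03_transcriptomics_link.R` (planted
ρ = 0.8 genes: sensitivity 0.93 against true age at n = 18 AOIs, null FPR
0.03), `04_lco_classification.R` (12/12 plaques typed correctly at SNR 20),
`05_radial_profiles.R` (planted LAMP1 decrease and HOMER1 dip recovered;
pooled HOMER1-vs-maturity r = −0.98), `06_summary.R` (power minima:
d = 2.5 → n = 3, d = 1.5 → n = 5 at α = 0.05, power 0.8) — writing their
tables under `results/`.

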