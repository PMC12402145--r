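#!/usr/bin/env Rscript
# Stage 2 — nitrogen indices from simulated spectra.
#
# LP mode: ALS baseline, asymmetric-Gaussian fit, FWHM as the index,
# R^2 > 0.90 QC. RP mode: 4th/3rd isotopologue peak-area ratio, checked
# against the exact theoretical pattern ratio.

suppressPackageStartupMessages(library(plaquetime))
seed <- 1L
out_dir <- "results/02_index"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

design <- labeling_design("pulse_chase")

## LP: age-rank recovery over seeded cohorts (SNR 20)
rhos <- vapply(seq_len(10), function(s) {
  co <- simulate_cohort(20, design, "LP", snr = 20, seed = seed * 100 + s)
  res <- lapply(co$spectra, nitrogen_index_lp)
  qc <- vapply(res, `[[`, logical(1), "qc_pass")
  cor(co$truth$age[qc], vapply(res, `[[`, numeric(1), "value")[qc],
      method = "spearman")
}, numeric(1))
cat(sprintf("LP index vs true plaque age: Spearman rho median %.3f (range %.3f-%.3f, 10 cohorts of 20, SNR 20)\n",
            median(rhos), min(rhos), max(rhos)))

co <- simulate_cohort(20, design, "LP", snr = 20, seed = seed)
res <- lapply(co$spectra, nitrogen_index_lp)
tab <- data.frame(co$truth,
                  fwhm = vapply(res, `[[`, numeric(1), "value"),
                  r_squared = vapply(res, `[[`, numeric(1), "r_squared"),
                  qc_pass = vapply(res, `[[`, logical(1), "qc_pass"))
write_index_table(tab, file.path(out_dir, "lp_indices.tsv"))

## RP: calibration against the exact isotopologue pattern
ab <- composition_from_sequence(ABETA42_SEQUENCE)
pl <- sim_plaque(10, design)
calib <- do.call(rbind, lapply(c(0, 0.05, 0.10, 0.15, 0.20, 0.25), function(q) {
  sp <- simulate_plaque_spectrum(pl, design, "RP", snr = Inf, seed = seed,
                                 q_override = max(q, 1e-12))
  th <- theoretical_peak_ratio(isotopologue_pattern(ab, enrichment_params(q)))
  data.frame(q = q, measured = nitrogen_index_rp(sp)$value, theoretical = th)
}))
calib$rel_err <- calib$measured / calib$theoretical - 1
write.table(calib, file.path(out_dir, "rp_calibration.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
cat(sprintf("RP 4th/3rd area ratio vs theory: max |rel err| %.4f over q = 0..0.25 (noiseless)\n",
            max(abs(calib$rel_err))))
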