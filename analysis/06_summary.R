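#!/usr/bin/env Rscript
# Stage 6 — design utilities and run summary.
#
# The a priori power minima behind the IHC group sizes, and the headline
# numbers from stages 2-5 gathered into one JSON.

suppressPackageStartupMessages(library(plaquetime))
out_dir <- "results"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

n_lamp1 <- min_n_power(2.5, alpha = 0.05, target_power = 0.8)
n_homer1 <- min_n_power(1.5, alpha = 0.05, target_power = 0.8)
cat(sprintf("power minima (alpha 0.05, power 0.8, one-sample one-sided): d = 2.5 -> n = %d; d = 1.5 -> n = %d\n",
            n_lamp1, n_homer1))

comp <- composition_from_sequence(ABETA42_SEQUENCE)
summary <- list(
  abeta42_monoisotopic_mh = round(monoisotopic_mz(comp, 1), 1),
  abeta42_nitrogens = unclass(comp)[["N"]],
  power_min_n_d2.5 = n_lamp1,
  power_min_n_d1.5 = n_homer1
)

# pull stage outputs if they exist
lp <- file.path(out_dir, "02_index", "lp_indices.tsv")
if (file.exists(lp)) {
  tab <- read.delim(lp)
  ok <- tab$qc_pass == "TRUE" | tab$qc_pass == TRUE
  summary$lp_age_spearman <- cor(tab$age[ok], tab$fwhm[ok],
                                 method = "spearman")
}
rp <- file.path(out_dir, "02_index", "rp_calibration.tsv")
if (file.exists(rp)) {
  summary$rp_max_rel_err <- max(abs(read.delim(rp)$rel_err))
}

jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("wrote results/summary.json\n")
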