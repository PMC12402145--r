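#!/usr/bin/env Rscript
# Stage 3 — single-plaque expression vs plaque age.
#
# 18 AOIs (the 18-month design), planted positive/negative genes at
# rho = 0.8: quantile normalization, gene-wise Pearson vs the measured LP
# index, volcano split at non-FDR p < 0.05, Fisher ORA on synthetic gene
# sets, and covariate/outlier checks.

suppressPackageStartupMessages(library(plaquetime))
seed <- 1L
out_dir <- "results/03_transcriptomics"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

design <- labeling_design("pulse_chase")
co <- simulate_cohort(18, design, "LP", snr = 20, seed = seed)
res <- lapply(co$spectra, nitrogen_index_lp)
idx <- vapply(res, `[[`, numeric(1), "value")
qc <- vapply(res, `[[`, logical(1), "qc_pass")

expr <- simulate_expression(200, ages = co$truth$age, n_planted_pos = 15,
                            n_planted_neg = 15, rho = 0.8, seed = seed + 1)
counts <- filter_low_counts(expr$counts)
qn <- quantile_normalize(counts[, qc, drop = FALSE])
cors <- correlate_gene_age(qn, idx[qc], design = "pulse_chase")
cors <- merge(cors, expr$truth, by = "gene")
write.table(cors, file.path(out_dir, "gene_age_correlations.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)

vs <- volcano_split(cors, p_cut = 0.05)
planted <- expr$truth$planted_sign[match(cors$gene, expr$truth$gene)]
sens <- mean((cors$p_two_sided < 0.05 &
                sign(cors$pearson_r) == planted)[planted != 0])
fpr <- mean(cors$p_two_sided[planted == 0] < 0.05)
cat(sprintf("volcano vs measured LP index: %d positive, %d negative genes at p < 0.05; planted-gene sensitivity %.2f, null FPR %.3f\n",
            length(vs$positive), length(vs$negative), sens, fpr))

## calibration: the same genes against the true ages they were planted on
## (the measured index is a nonlinear, noisy readout of age, so the
## index-based sensitivity above is attenuated relative to this ceiling)
cal <- correlate_gene_age(quantile_normalize(counts), co$truth$age,
                          design = "pulse_chase")
pl2 <- expr$truth$planted_sign[match(cal$gene, expr$truth$gene)]
sens_cal <- mean((cal$p_two_sided < 0.05 &
                    sign(cal$pearson_r) == pl2)[pl2 != 0])
cat(sprintf("calibration vs true age: planted-gene sensitivity %.2f\n",
            sens_cal))

## ORA against synthetic gene sets: one concentrated in planted-positive
## genes, one in nulls
bg <- rownames(counts)
pos_genes <- expr$truth$gene[expr$truth$planted_sign == 1]
null_genes <- expr$truth$gene[expr$truth$planted_sign == 0]
sets <- list(age_up_module = pos_genes,
             housekeeping = null_genes[1:30])
ora <- ora_fisher(vs$positive, sets, bg)
write.table(ora, file.path(out_dir, "ora_results.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
cat(sprintf("ORA: '%s' enriched (p = %.2e, q = %.2e); '%s' %s\n",
            ora$set[1], ora$p[1], ora$q[1], ora$set[2],
            ifelse(ora$enriched[2], "enriched", "not enriched")))

## covariates: AOI area / cell count / GFAP fraction independent of age by
## construction, so the index should not correlate with them
set.seed(seed + 2)
md <- data.frame(aoi_area = runif(sum(qc), 5e3, 2e4),
                 cell_count = rpois(sum(qc), 60),
                 gfap_area_fraction = runif(sum(qc), 0.05, 0.4))
cov <- covariate_check(md, idx[qc])
write.table(cov, file.path(out_dir, "covariate_check.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
cat(sprintf("covariates: max |r| = %.2f, min p = %.2f (none expected significant)\n",
            max(abs(cov$pearson_r)), min(cov$p_two_sided)))

## Grubbs outlier screen on the index values
out <- grubbs_outlier(idx[qc], alpha = 0.01)
cat(sprintf("Grubbs screen on indices: %d outlier(s) flagged\n", length(out)))
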