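# End-to-end seeded workflow over synthetic data: spectra -> nitrogen
# indices -> expression correlations -> LCO classification -> radial rings.

#' Pipeline configuration
#'
#' Collects every tunable the workflow uses; the resolved config is written
#' alongside the outputs so a run is reproducible from its directory.
#'
#' @param seed Integer master seed.
#' @param design_kind `"pulse_chase"` or `"pulse_only"`.
#' @param n_plaques Cohort size.
#' @param snr Spectrum signal-to-noise ratio.
#' @param mode Acquisition mode for the index branch, `"LP"` or `"RP"`.
#' @param als ALS parameters (list: lambda (log10 exponent; NULL = the
#'   mode's default, 7 for LP and 5 for RP), p, maxit).
#' @param r2_min LP QC floor on R^2.
#' @param n_genes,n_planted_pos,n_planted_neg,rho Expression branch.
#' @param p_cut,q_cut Volcano / ORA cutoffs.
#' @param ring_increment_um,ring_max_um Ring geometry.
#' @param noise_sd Hyperspectral channel noise.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1L, design_kind = "pulse_chase",
                       n_plaques = 12L, snr = 20, mode = "LP",
                       als = list(lambda = NULL, p = 0.025, maxit = 100L),
                       r2_min = 0.90, n_genes = 120L, n_planted_pos = 8L,
                       n_planted_neg = 8L, rho = 0.8, p_cut = 0.05,
                       q_cut = 0.05, ring_increment_um = 10,
                       ring_max_um = 30, noise_sd = 0.02) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Run the full correlative workflow on synthetic data
#'
#' Three branches, joined on plaque id: (1) simulated plaque spectra to
#' nitrogen indices, with center-vs-periphery and cortex-vs-hippocampus
#' contrasts; (2) plaque-age-correlated expression to volcano gene lists;
#' (3) hyperspectral LCO unmixing/classification and radial IHC ring
#' profiles. If `out_dir` is given, tables are written as TSV plus the
#' resolved config as JSON.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory (created if needed).
#' @return List of data.frames: `indices`, `contrasts`, `gene_correlations`,
#'   `volcano`, `plaque_classes`, `class_fractions`, `ring_profiles`,
#'   `joined`, plus `config`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  design <- labeling_design(config$design_kind)

  # --- branch 1: spectra -> nitrogen index ---------------------------------
  cohort <- simulate_cohort(config$n_plaques, design, mode = config$mode,
                            snr = config$snr, seed = config$seed)
  lam <- config$als$lambda
  idx_fun <- if (config$mode == "LP") {
    function(sp) nitrogen_index_lp(sp, lambda = if (is.null(lam)) 7 else lam,
                                   p = config$als$p, maxit = config$als$maxit,
                                   r2_min = config$r2_min)
  } else {
    function(sp) nitrogen_index_rp(sp, lambda = if (is.null(lam)) 5 else lam,
                                   p = config$als$p, maxit = config$als$maxit)
  }
  idx <- lapply(cohort$spectra, idx_fun)
  indices <- data.frame(
    roi_id = cohort$truth$roi_id,
    region = cohort$truth$region,
    mode = config$mode,
    value = vapply(idx, `[[`, numeric(1), "value"),
    qc_pass = vapply(idx, `[[`, logical(1), "qc_pass"),
    true_age = cohort$truth$age,
    true_q_bar = cohort$truth$q_bar)
  if (config$mode == "LP") {
    indices$r_squared <- vapply(idx, function(i)
      if (is.null(i$r_squared)) NA_real_ else i$r_squared, numeric(1))
  }

  # center vs periphery truth contrast (paired over plaques), and
  # cortex vs hippocampus on measured indices
  cen <- vapply(seq_len(config$n_plaques), function(i) {
    plaque_mean_enrichment(sim_plaque(cohort$truth$birth_time[i], design),
                           design, "center")
  }, numeric(1))
  per <- vapply(seq_len(config$n_plaques), function(i) {
    plaque_mean_enrichment(sim_plaque(cohort$truth$birth_time[i], design),
                           design, "periphery")
  }, numeric(1))
  cp <- paired_t(cen, per)
  reg_split <- split(indices$value[indices$qc_pass],
                     indices$region[indices$qc_pass])
  reg_p <- if (length(reg_split) == 2 && all(lengths(reg_split) >= 2)) {
    stats::t.test(reg_split[[1]], reg_split[[2]])$p.value
  } else NA_real_
  contrasts <- data.frame(
    contrast = c("center_vs_periphery_enrichment", "cortex_vs_hippocampus_index"),
    statistic = c(cp$t, NA_real_),
    p_two_sided = c(cp$p_two_sided, reg_p),
    direction = c(if (mean(cen) < mean(per)) "center<periphery"
                  else "center>=periphery", "two-sided"))

  # --- branch 2: expression ------------------------------------------------
  ok <- indices$qc_pass & !is.na(indices$value)
  gene_correlations <- NULL
  volcano <- NULL
  if (sum(ok) >= 4) {
    expr <- simulate_expression(config$n_genes, ages = indices$true_age[ok],
                                n_planted_pos = config$n_planted_pos,
                                n_planted_neg = config$n_planted_neg,
                                rho = config$rho, seed = config$seed + 1L)
    qn <- quantile_normalize(filter_low_counts(expr$counts))
    gene_correlations <- correlate_gene_age(qn, indices$value[ok],
                                            design = config$design_kind)
    gene_correlations <- merge(gene_correlations, expr$truth, by = "gene",
                               sort = TRUE)
    vs <- volcano_split(gene_correlations, config$p_cut)
    volcano <- data.frame(
      gene = c(vs$positive, vs$negative),
      direction = c(rep("positive", length(vs$positive)),
                    rep("negative", length(vs$negative))))
  }

  # --- branch 3: LCO + IHC -------------------------------------------------
  ages01 <- (indices$true_age - min(indices$true_age)) /
    max(diff(range(indices$true_age)), 1e-9)
  classes <- c("hq", "h", "none")[1 + (seq_len(config$n_plaques) %% 3)]
  hs <- simulate_hyperspectral(config$n_plaques, ages = ages01,
                               classes = classes, noise_sd = config$noise_sd,
                               seed = config$seed + 2L)
  um <- linear_unmix(hs$image, hs$refs)
  objs <- segment_plaques(hs$abeta, hs$pixel_size, min_area_um2 = 10)
  objs <- classify_plaques(objs, um$a_q, um$a_h,
                           q_thresh = 0.10, h_thresh = 0.10)
  plaque_classes <- data.frame(
    id = vapply(objs, `[[`, integer(1), "id"),
    x_um = vapply(objs, function(o) o$centroid_um[["x"]], numeric(1)),
    y_um = vapply(objs, function(o) o$centroid_um[["y"]], numeric(1)),
    area_um2 = vapply(objs, `[[`, numeric(1), "area_um2"),
    class = vapply(objs, `[[`, character(1), "class"),
    core_ratio = vapply(objs, function(o)
      core_ratio(o$mask, hs$image, hs$refs$wavelengths), numeric(1)))
  class_fractions <- if (length(objs) > 0) class_area_fractions(objs) else NULL

  ihc <- simulate_ihc(classes = classes, noise_sd = 2,
                      seed = config$seed + 3L)
  rs <- lapply(ihc$masks, build_rings, pixel_size = ihc$pixel_size,
               increment_um = config$ring_increment_um,
               max_um = config$ring_max_um)
  rs <- remove_overlaps(rs)
  ring_profiles <- do.call(rbind, lapply(names(ihc$channels), function(ch) {
    rm_ <- ring_means(ihc$channels[[ch]], rs)
    rm_$channel <- ch
    rm_$class <- ihc$classes[rm_$plaque]
    rm_
  }))

  # --- join on plaque id ---------------------------------------------------
  joined <- indices
  joined$lco_class <- classes
  joined$sim_age01 <- ages01

  result <- list(indices = indices, contrasts = contrasts,
                 gene_correlations = gene_correlations, volcano = volcano,
                 plaque_classes = plaque_classes,
                 class_fractions = class_fractions,
                 ring_profiles = ring_profiles, joined = joined,
                 config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in setdiff(names(result), "config")) {
      if (is.data.frame(result[[nm]])) {
        utils::write.table(result[[nm]], file.path(out_dir,
                                                   paste0(nm, ".tsv")),
                           sep = "\t", row.names = FALSE, quote = FALSE)
      }
    }
    jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  result
}
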