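# Seeded generators for labeled-plaque MALDI spectra with known ground truth.
#
# Body-pool 15N enrichment follows first-order rise during the labeled-diet
# pulse and first-order washout during the chase. A plaque deposits material
# at a constant rate from its birth until cull; its spectrum is the
# deposition-weighted mixture of isotopologue patterns at the enrichment
# prevailing at each deposition time, convolved with the instrument response.

# Run code under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Labeling design for the 15N pulse(-chase) experiment
#'
#' The study design: labeled diet between 6 and 10 months of age; the
#' 10-month group is culled at the end of the pulse (pulse-only), the
#' 18-month group after an 8-month unlabeled chase (pulse-chase).
#'
#' @param kind `"pulse_only"` or `"pulse_chase"`.
#' @param pulse_start,pulse_end Months of age (defaults 6 and 10).
#' @param cull_time Months at cull; defaults 10 (pulse-only) or 18
#'   (pulse-chase).
#' @param e_max Plateau body-pool 15N fraction (default 0.25).
#' @param k_in,k_out First-order rise and washout rates, 1/month
#'   (defaults 3 and 1).
#' @param onset Age in months at which the first plaques appear (default 9).
#' @param deposition_decay Rate (1/month) at which a plaque's deposition
#'   rate declines with its own age (default 1): plaque growth saturates, so
#'   most material is laid down soon after birth — the growth-ring picture
#'   in which the core holds the first-deposited material. 0 gives a
#'   constant deposition rate.
#' @return List of class `labeling_design`.
#' @export
labeling_design <- function(kind = c("pulse_chase", "pulse_only"),
                            pulse_start = 6, pulse_end = 10,
                            cull_time = NULL, e_max = 0.25,
                            k_in = 3, k_out = 1, onset = 9,
                            deposition_decay = 1) {
  kind <- match.arg(kind)
  if (is.null(cull_time)) cull_time <- if (kind == "pulse_only") 10 else 18
  stopifnot(pulse_start < pulse_end, pulse_end <= cull_time,
            e_max > 0, e_max <= 1, k_in > 0, k_out > 0,
            onset >= pulse_start, onset <= cull_time, deposition_decay >= 0)
  structure(list(kind = kind, pulse_start = pulse_start,
                 pulse_end = pulse_end, cull_time = cull_time,
                 e_max = e_max, k_in = k_in, k_out = k_out, onset = onset,
                 deposition_decay = deposition_decay),
            class = "labeling_design")
}

#' Body-pool 15N enrichment at time t
#'
#' Rises as e_max * (1 - exp(-k_in (t - pulse_start))) above natural
#' abundance during the pulse and decays as exp(-k_out (t - pulse_end))
#' during the chase; before the pulse it equals natural abundance.
#'
#' @param t Age in months (vectorized).
#' @param design A [labeling_design()].
#' @return 15N fraction (natural abundance 0.00364 is the floor).
#' @export
body_enrichment <- function(t, design) {
  q_nat <- .Q_NATURAL_15N
  rise <- function(tt) {
    (design$e_max - q_nat) * (1 - exp(-design$k_in * (tt - design$pulse_start)))
  }
  above <- ifelse(t < design$pulse_start, 0,
           ifelse(t <= design$pulse_end, rise(t),
                  rise(design$pulse_end) * exp(-design$k_out * (t - design$pulse_end))))
  q_nat + above
}

#' Define a simulated plaque
#'
#' @param birth_time Age (months) at which deposition starts; must lie in
#'   [design onset, cull].
#' @param design A [labeling_design()].
#' @param region `"cortex"` or `"hippocampus"` label.
#' @param roi_id Identifier.
#' @return List of class `sim_plaque` with `birth_time`, `age`
#'   (cull - birth) and labels.
#' @export
sim_plaque <- function(birth_time, design, region = "hippocampus",
                       roi_id = NA_character_) {
  stopifnot(birth_time >= design$pulse_start, birth_time <= design$cull_time)
  structure(list(birth_time = birth_time,
                 age = design$cull_time - birth_time,
                 region = region, roi_id = roi_id),
            class = "sim_plaque")
}

# Deposition-time quadrature for a plaque sub-ROI. Center material is the
# earliest third of [birth, cull], periphery the latest third (growth-ring
# simplification; "whole" spans the full interval). Returns times and
# deposition weights (rate declines at design$deposition_decay per month of
# plaque age).
.deposition_times <- function(plaque, design, subregion = "whole", n_t = 15L) {
  b <- plaque$birth_time
  cu <- design$cull_time
  if (cu - b < 1e-9) return(list(t = rep(b, n_t), w = rep(1 / n_t, n_t)))
  span <- switch(subregion,
                 center = c(b, b + (cu - b) / 3),
                 periphery = c(cu - (cu - b) / 3, cu),
                 whole = c(b, cu),
                 stop("subregion must be center, periphery or whole"))
  tt <- seq(span[1], span[2], length.out = n_t)
  w <- exp(-design$deposition_decay * (tt - b))
  list(t = tt, w = w / sum(w))
}

#' Deposition-weighted mean enrichment of a plaque sub-ROI
#'
#' @param plaque A [sim_plaque()].
#' @param design A [labeling_design()].
#' @param subregion `"whole"`, `"center"` or `"periphery"`.
#' @param n_t Quadrature nodes over the deposition interval.
#' @return Mean 15N fraction of the deposited material.
#' @export
plaque_mean_enrichment <- function(plaque, design, subregion = "whole",
                                   n_t = 15L) {
  dep <- .deposition_times(plaque, design, subregion, n_t)
  sum(dep$w * body_enrichment(dep$t, design))
}

#' Deposition-weighted mixture isotopologue pattern
#'
#' Average of theoretical patterns at each enrichment, weighted by
#' deposition weights. The non-nitrogen part of the pattern is computed once
#' and convolved with the per-enrichment binomial nitrogen channel.
#'
#' @param comp Composition.
#' @param qs Vector of 15N fractions.
#' @param weights Mixture weights (default uniform).
#' @param prune Abundance pruning threshold.
#' @param charge Charge state.
#' @return An `isotopologue_pattern` of the mixture.
#' @export
isotopologue_mixture <- function(comp, qs, weights = NULL, prune = 1e-10,
                                 charge = 1L) {
  if (is.null(weights)) weights <- rep(1, length(qs))
  weights <- weights / sum(weights)
  comp_u <- unclass(comp)
  n_n <- comp_u[["N"]]
  # base pattern of the C/H/O/S part, unpruned enough for mixing
  base_comp <- comp_u
  base_comp[["N"]] <- 0L
  acc <- list(p = 1, s = 0)
  for (el in setdiff(names(.ISOTOPES), "N")) {
    n <- base_comp[[el]]
    if (is.na(n) || n == 0L) next
    acc <- .conv_pm(acc, .conv_power(.element_pm(.ISOTOPES[[el]]), n,
                                     prune = prune / 10), prune = prune / 10)
  }
  mix <- NULL
  for (k in seq_along(qs)) {
    q <- qs[k]
    nit <- .conv_power(list(p = c(1 - q, q), s = c(0, q * .DELTA_15N)),
                       n_n, prune = prune / 10)
    pat <- .conv_pm(acc, nit, prune = prune / 10)
    if (is.null(mix)) {
      mix <- list(p = weights[k] * pat$p, s = weights[k] * pat$s)
    } else {
      len <- max(length(mix$p), length(pat$p))
      pad <- function(v, l) c(v, rep(0, l - length(v)))
      mix <- list(p = pad(mix$p, len) + weights[k] * pad(pat$p, len),
                  s = pad(mix$s, len) + weights[k] * pad(pat$s, len))
    }
  }
  keep <- which(mix$p > prune)
  idx <- keep[1]:max(keep)
  p <- mix$p[idx]; s <- mix$s[idx]
  mono <- monoisotopic_mz(comp_u, charge)
  masses <- mono + ifelse(p > 0, s / p, idx - 1) / charge
  structure(list(masses = masses, abundances = p / sum(p),
                 offsets = idx - 1L,
                 enrichment_q = sum(weights * qs)),
            class = "isotopologue_pattern")
}

# Instrument reference points: LP resolution quoted at m/z 4515, RP at 4512.3.
.instrument_fwhm <- function(mode, resolving_power) {
  ref <- if (mode == "LP") 4515 else 4512.3
  ref / resolving_power
}

#' Simulate one plaque-ROI spectrum
#'
#' Renders the deposition-weighted mixture pattern of A-beta 1-42 on an m/z
#' grid, convolved with a Gaussian instrument response (FWHM =
#' m/resolving_power at the reference m/z), plus a smooth exponential
#' chemical background and Gaussian noise. Background and noise amplitudes
#' both scale as 1/snr, so `snr = Inf` yields the clean trace.
#'
#' @param plaque A [sim_plaque()].
#' @param design A [labeling_design()].
#' @param mode `"LP"` or `"RP"`.
#' @param snr Signal-to-noise ratio (max signal / noise sd); `Inf` for
#'   noiseless.
#' @param seed Integer seed.
#' @param subregion `"whole"`, `"center"` or `"periphery"`.
#' @param resolving_power Defaults 1000 (LP) / 15000 (RP).
#' @param q_override Optional single enrichment replacing the kinetic
#'   mixture (for calibration spectra at known q).
#' @param n_t Deposition quadrature nodes.
#' @return A [spectrum()] with attribute `"truth"` (list: q_bar, birth_time,
#'   age, subregion, pattern).
#' @export
simulate_plaque_spectrum <- function(plaque, design, mode = c("LP", "RP"),
                                     snr = 20, seed = 1L,
                                     subregion = "whole",
                                     resolving_power = NULL,
                                     q_override = NULL, n_t = 15L) {
  mode <- match.arg(mode)
  stopifnot(snr > 0)
  if (is.null(resolving_power)) resolving_power <- if (mode == "LP") 1000 else 15000
  comp <- composition_from_sequence(ABETA42_SEQUENCE)
  if (is.null(q_override)) {
    dep <- .deposition_times(plaque, design, subregion, n_t)
    qs <- body_enrichment(dep$t, design)
    wt <- dep$w
  } else {
    qs <- q_override
    wt <- NULL
  }
  pat <- isotopologue_mixture(comp, qs, wt, prune = 1e-9)
  mono <- monoisotopic_mz(comp, 1L)
  fwhm_inst <- .instrument_fwhm(mode, resolving_power)
  sigma_inst <- fwhm_inst / (2 * sqrt(2 * log(2)))
  # grid steps mirror TOF digitization at m/z ~4500: much finer than the
  # instrument peak width in either mode
  if (mode == "LP") {
    mz <- seq(mono - 20, mono + 40, by = 0.05)
  } else {
    mz <- seq(mono - 3, mono + 28, by = 0.01)
  }
  signal <- rep(0, length(mz))
  for (k in seq_along(pat$masses)) {
    signal <- signal + pat$abundances[k] *
      exp(-(mz - pat$masses[k])^2 / (2 * sigma_inst^2))
  }
  smax <- max(signal)
  intensity <- .with_seed(seed, {
    bg <- if (is.finite(snr)) {
      2 * smax / snr * exp(-(mz - mz[1]) / 15)
    } else 0
    noise <- if (is.finite(snr)) stats::rnorm(length(mz), 0, smax / snr) else 0
    pmax(signal + bg + noise, 0)
  })
  sp <- spectrum(mz, intensity, mode = mode,
                 resolving_power = resolving_power,
                 roi_id = plaque$roi_id, region = plaque$region,
                 subregion = subregion)
  attr(sp, "truth") <- list(q_bar = if (is.null(wt)) mean(qs) else sum(wt * qs),
                            birth_time = plaque$birth_time,
                            age = plaque$age, subregion = subregion,
                            pattern = pat)
  sp
}

#' Simulate a cohort of plaque spectra with ground truth
#'
#' Plaque birth times are uniform on [pathology onset, cull]; each plaque's
#' spectrum gets its own sub-seed derived from `seed`.
#'
#' @param n_plaques Number of plaques (>= 2).
#' @param design A [labeling_design()].
#' @param mode `"LP"` or `"RP"`.
#' @param snr Signal-to-noise ratio.
#' @param seed Integer seed.
#' @param subregion Sub-ROI to render.
#' @return List with `spectra` (list of [spectrum()]) and `truth`
#'   (data.frame: roi_id, region, birth_time, age, q_bar).
#' @export
simulate_cohort <- function(n_plaques = 20L, design = labeling_design(),
                            mode = c("LP", "RP"), snr = 20, seed = 1L,
                            subregion = "whole") {
  mode <- match.arg(mode)
  stopifnot(n_plaques >= 2)
  births <- .with_seed(seed, stats::runif(n_plaques, design$onset,
                                          design$cull_time))
  regions <- rep(c("hippocampus", "cortex"), length.out = n_plaques)
  spectra <- vector("list", n_plaques)
  truth <- data.frame(roi_id = sprintf("plaque_%02d", seq_len(n_plaques)),
                      region = regions, birth_time = births,
                      age = design$cull_time - births,
                      q_bar = NA_real_)
  for (i in seq_len(n_plaques)) {
    pl <- sim_plaque(births[i], design, region = regions[i],
                     roi_id = truth$roi_id[i])
    spectra[[i]] <- simulate_plaque_spectrum(
      pl, design, mode = mode, snr = snr,
      seed = seed * 1000L + i, subregion = subregion)
    truth$q_bar[i] <- attr(spectra[[i]], "truth")$q_bar
  }
  list(spectra = spectra, truth = truth, design = design)
}
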