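# ALS baseline, peak detection, asymmetric-Gaussian fitting and the LP/RP
# nitrogen indices.

test_that("ALS baseline reproduces flat and zero signals exactly", {
  y <- rep(3.2, 50)
  bl <- als_baseline(list(intensity = y), lambda = 5)
  expect_true(all(abs(bl$baseline - 3.2) < 1e-6))
  bl0 <- als_baseline(list(intensity = rep(0, 50)))
  expect_true(all(bl0$baseline == 0))
  expect_true(all(bl0$corrected == 0))
  expect_error(als_baseline(list(intensity = rep(1, 5))), "8 points")
})

test_that("ALS baseline recovers a linear drift under a narrow peak", {
  # background-dominated fixture: drift 2-4 units, unit peak, SNR 50
  set.seed(11)
  x <- seq(0, 100, by = 0.25)
  drift <- 2 + 0.02 * x
  y <- drift + asym_gauss_trace(x, 1, 50, 0.8, 0.8) + rnorm(length(x), 0, 1 / 50)
  bl <- als_baseline(list(intensity = y), lambda = 7)
  peak_free <- abs(x - 50) > 5
  rel_err <- abs(bl$baseline[peak_free] - drift[peak_free]) / drift[peak_free]
  expect_lt(max(rel_err), 0.02)
})

test_that("ALS corrected signal is non-negative and baseline stays under the signal ceiling", {
  set.seed(3)
  y <- pmax(rnorm(200, 1, 0.3), 0)
  bl <- als_baseline(list(intensity = y))
  expect_true(all(bl$corrected >= 0))
  expect_true(all(bl$baseline <= cummax(y) + 1e-8))
})

test_that("local maxima detection matches the neighbor rule with plateau ties at the lowest index", {
  expect_identical(detect_peaks(c(0, 1, 0, 2, 0)), c(2L, 4L))
  expect_identical(detect_peaks(1:10), integer(0))
  expect_identical(detect_peaks(c(0, 2, 2, 0)), 2L)
  expect_identical(detect_peaks(c(1, 0, 3, 3, 3, 1, 0)), 3L)
})

test_that("main-peak selection takes the most intense apex, ties to lowest m/z", {
  expect_identical(select_main_peak(c(2L, 4L), c(0, 3, 0, 3, 0)), 2L)
  expect_identical(select_main_peak(c(2L, 4L), c(0, 1, 0, 5, 0)), 4L)
  expect_error(select_main_peak(integer(0), c(0, 1, 0)), "no local maxima")
})

test_that("fitting window defaults to 3x the instrument FWHM and clips at edges", {
  mz <- seq(4490, 4540, by = 0.1)
  y <- asym_gauss_trace(mz, 1, 4515, 2, 2)
  sp <- spectrum(mz, y, "LP", resolving_power = 1000)
  apex <- which.max(y)
  win <- fit_window(sp, apex)
  expect_equal(max(win$mz) - sp$mz[apex], 3 * 4515 / 1000, tolerance = 0.11)
  expect_false(win$clipped)
  sp2 <- spectrum(seq(4510, 4520, by = 0.1), rep(1, 101), "LP")
  win2 <- fit_window(sp2, 5L, half_width = 3)
  expect_true(win2$clipped)
  expect_error(fit_window(sp, apex, half_width = 0.2), "6 points")
})

test_that("asymmetric Gaussian fit recovers noiseless parameters to solver tolerance", {
  mz <- seq(4490, 4540, by = 0.05)
  sym <- fit_asymmetric_gaussian(list(mz = mz,
                                      intensity = asym_gauss_trace(mz, 1, 4515, 2, 2)))
  expect_equal(sym$sigma_left, 2, tolerance = 1e-3)
  expect_equal(sym$sigma_right, 2, tolerance = 1e-3)
  expect_equal(sym$fwhm, 2 * sqrt(2 * log(2)) * 2, tolerance = 1e-3)
  asym <- fit_asymmetric_gaussian(list(mz = mz,
                                       intensity = asym_gauss_trace(mz, 0.8, 4512, 1.5, 3)))
  expect_equal(asym$sigma_left, 1.5, tolerance = 1e-2)
  expect_equal(asym$sigma_right, 3.0, tolerance = 1e-2)
  expect_true(asym$converged)
  expect_gt(asym$r_squared, 0.999)
})

test_that("LP index pipeline: QC rejects flat noise, accepts clean envelopes", {
  set.seed(21)
  mz <- seq(4490, 4540, by = 0.05)
  flat <- spectrum(mz, abs(rnorm(length(mz), 0, 1)), "LP")
  ni <- nitrogen_index_lp(flat)
  expect_false(ni$qc_pass)
  des <- labeling_design("pulse_chase")
  sp <- simulate_plaque_spectrum(sim_plaque(10, des), des, "LP", snr = 20,
                                 seed = 5)
  ni2 <- nitrogen_index_lp(sp)
  expect_true(ni2$qc_pass)
  expect_gt(ni2$r_squared, 0.90)
  expect_gt(ni2$value, 0)
})

test_that("LP pipeline reproduces a pure asymmetric-Gaussian input within the documented baseline systematic", {
  mz <- seq(4490, 4540, by = 0.05)
  sp <- spectrum(mz, asym_gauss_trace(mz, 0.8, 4515, 2, 3.5), "LP")
  truth <- sqrt(2 * log(2)) * (2 + 3.5)
  ni <- nitrogen_index_lp(sp)
  # ALS removes some mass under any finite peak; narrowing is bounded and
  # shrinks as the baseline stiffens
  expect_lt(abs(ni$value - truth) / truth, 0.12)
  ni9 <- nitrogen_index_lp(sp, lambda = 9)
  expect_lt(abs(ni9$value - truth) / truth, 0.025)
  expect_lt(abs(ni9$value - truth), abs(ni$value - truth))
})

test_that("LP FWHM rises monotonically with enrichment", {
  des <- labeling_design("pulse_chase")
  pl <- sim_plaque(10, des)
  # strict monotonicity is a property of the signal (binomial variance
  # n q (1 - q) increases on q < 0.5): assert it on clean envelopes
  fwhm <- vapply(seq(0.05, 0.40, by = 0.05), function(q) {
    sp <- simulate_plaque_spectrum(pl, des, "LP", snr = Inf, seed = 7,
                                   q_override = q)
    nitrogen_index_lp(sp)$value
  }, numeric(1))
  expect_true(all(diff(fwhm) > 0))
  # at SNR 20 the ordering holds for separated enrichments
  noisy <- vapply(c(0.05, 0.15, 0.30), function(q) {
    sp <- simulate_plaque_spectrum(pl, des, "LP", snr = 20, seed = 7,
                                   q_override = q)
    nitrogen_index_lp(sp)$value
  }, numeric(1))
  expect_true(all(diff(noisy) > 0))
})

test_that("RP index requires resolvable isotopologues and a reachable ladder", {
  des <- labeling_design("pulse_chase")
  sp <- simulate_plaque_spectrum(sim_plaque(10, des), des, "RP", snr = Inf,
                                 seed = 1, q_override = 0.1)
  low_res <- sp
  low_res$resolving_power <- 1000
  ni <- nitrogen_index_rp(low_res)
  expect_false(ni$qc_pass)
  expect_match(ni$reason, "unresolvable")
  # truncated axis: ladder runs out of range
  keep <- sp$mz > 4516
  trunc <- spectrum(sp$mz[keep], sp$intensity[keep], "RP")
  ni2 <- nitrogen_index_rp(trunc)
  expect_false(ni2$qc_pass)
})

test_that("RP index matches the theoretical pattern ratio on clean spectra", {
  des <- labeling_design("pulse_chase")
  pl <- sim_plaque(10, des)
  ab <- abeta_comp()
  for (q in c(0.00364, 0.10)) {
    sp <- simulate_plaque_spectrum(pl, des, "RP", snr = Inf, seed = 1,
                                   q_override = q)
    ni <- nitrogen_index_rp(sp)
    th <- theoretical_peak_ratio(isotopologue_pattern(ab, enrichment_params(q)))
    expect_true(ni$qc_pass)
    expect_equal(ni$value, th, tolerance = 0.02)
  }
})

test_that("both indices rank two plaques of different enrichment consistently", {
  des <- labeling_design("pulse_chase")
  pl <- sim_plaque(10, des)
  # noiseless ranking across each index's physical range: LP to q = 0.4;
  # RP to q = 0.25 (beyond that the 3rd/4th isotopologue abundances fall
  # below the pattern's dynamic range and the area ratio is undefined)
  lp_clean <- vapply(c(0.05, 0.2, 0.4), function(q) {
    nitrogen_index_lp(simulate_plaque_spectrum(pl, des, "LP", snr = Inf,
                                               seed = 13,
                                               q_override = q))$value
  }, numeric(1))
  expect_true(all(diff(lp_clean) > 0))
  rp_clean <- vapply(c(0.05, 0.15, 0.25), function(q) {
    nitrogen_index_rp(simulate_plaque_spectrum(pl, des, "RP", snr = Inf,
                                               seed = 13,
                                               q_override = q))$value
  }, numeric(1))
  expect_true(all(diff(rp_clean) > 0))
  # at SNR 20 each index ranks enrichments within its informative range
  # (RP's 3rd/4th isotopologues fall below any finite noise floor at high q)
  lp <- vapply(c(0.08, 0.30), function(q) {
    nitrogen_index_lp(simulate_plaque_spectrum(pl, des, "LP", snr = 20,
                                               seed = 13,
                                               q_override = q))$value
  }, numeric(1))
  expect_lt(lp[1], lp[2])
  rp <- vapply(c(0.03, 0.12), function(q) {
    nitrogen_index_rp(simulate_plaque_spectrum(pl, des, "RP", snr = 20,
                                               seed = 13,
                                               q_override = q))$value
  }, numeric(1))
  expect_lt(rp[1], rp[2])
})

test_that("TIC normalization rescales to unit total and spectra validate inputs", {
  sp <- spectrum(1:10, rep(2, 10), "LP")
  expect_equal(sum(tic_normalize(sp)$intensity), 1)
  expect_error(spectrum(c(1, 2, 2, 3, 4, 5, 6, 7), rep(1, 8), "LP"),
               "increasing")
  expect_error(spectrum(1:4, rep(1, 4), "LP"))
})
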