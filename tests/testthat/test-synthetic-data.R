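# Ground-truth generators: labeling kinetics, spectra, expression,
# hyperspectral images and IHC channels.

test_that("body enrichment follows first-order rise and washout", {
  des <- labeling_design("pulse_chase", k_in = 2)
  q_nat <- body_enrichment(des$pulse_start - 1, des)
  expect_equal(q_nat, 0.00364)
  expect_equal(body_enrichment(des$pulse_start, des), q_nat)
  expect_equal(body_enrichment(des$pulse_start + 100, labeling_design(
    "pulse_chase", pulse_end = 200, cull_time = 300)), des$e_max,
    tolerance = 1e-6)
  # closed form one month into the pulse
  expect_equal(body_enrichment(des$pulse_start + 1, des) - q_nat,
               (des$e_max - q_nat) * (1 - exp(-2)), tolerance = 1e-12)
  # washout decays toward natural abundance
  late <- body_enrichment(c(11, 14, 18), des)
  expect_true(all(diff(late) < 0))
})

test_that("simulators are pure functions of parameters and seed", {
  des <- labeling_design("pulse_chase")
  c1 <- simulate_cohort(5, des, "LP", snr = 20, seed = 42)
  c2 <- simulate_cohort(5, des, "LP", snr = 20, seed = 42)
  expect_identical(c1$truth, c2$truth)
  expect_identical(lapply(c1$spectra, `[[`, "intensity"),
                   lapply(c2$spectra, `[[`, "intensity"))
  e1 <- simulate_expression(30, ages = 1:8, seed = 7)
  e2 <- simulate_expression(30, ages = 1:8, seed = 7)
  expect_identical(e1$counts, e2$counts)
  h1 <- simulate_hyperspectral(3, seed = 9)
  h2 <- simulate_hyperspectral(3, seed = 9)
  expect_identical(h1$image, h2$image)
  i1 <- simulate_ihc(c("hq", "h"), noise_sd = 1, seed = 4)
  i2 <- simulate_ihc(c("hq", "h"), noise_sd = 1, seed = 4)
  expect_identical(i1$channels, i2$channels)
})

test_that("center material is less enriched than periphery under pulse-only labeling", {
  des <- labeling_design("pulse_only")
  pl <- sim_plaque(9.2, des)
  expect_lt(plaque_mean_enrichment(pl, des, "center"),
            plaque_mean_enrichment(pl, des, "periphery"))
})

test_that("under pulse-chase, older plaques carry more label and centers exceed peripheries", {
  des <- labeling_design("pulse_chase")
  old <- sim_plaque(9.5, des)   # born during the pulse
  young <- sim_plaque(16, des)  # born deep into the chase
  expect_gt(plaque_mean_enrichment(old, des), plaque_mean_enrichment(young, des))
  expect_gt(plaque_mean_enrichment(old, des, "center"),
            plaque_mean_enrichment(old, des, "periphery"))
})

test_that("mixture centroid matches the closed-form enrichment mapping", {
  des <- labeling_design("pulse_chase")
  ab <- abeta_comp()
  nat_centroid <- pattern_centroid(isotopologue_pattern(ab))
  for (birth in c(9.5, 12, 16)) {
    sp <- simulate_plaque_spectrum(sim_plaque(birth, des), des, "LP",
                                   snr = Inf, seed = 1)
    truth <- attr(sp, "truth")
    shift <- pattern_centroid(truth$pattern) - nat_centroid
    expect_equal(shift, 55 * (truth$q_bar - 0.00364) * 0.99703,
                 tolerance = 0.05)
  }
})

test_that("RP index recovers the mixture's theoretical ratio on clean spectra", {
  des <- labeling_design("pulse_chase")
  sp <- simulate_plaque_spectrum(sim_plaque(10, des), des, "RP", snr = Inf,
                                 seed = 2)
  truth <- attr(sp, "truth")
  th <- theoretical_peak_ratio(truth$pattern, 4, 3)
  expect_equal(nitrogen_index_rp(sp)$value, th, tolerance = 0.02)
})

test_that("cohort truth spans the design interval and age ranks are recoverable", {
  des <- labeling_design("pulse_chase")
  co <- simulate_cohort(20, des, "LP", snr = 20, seed = 3)
  expect_true(all(co$truth$birth_time >= des$onset &
                    co$truth$birth_time <= des$cull_time))
  expect_true(all(diff(order(co$truth$birth_time)) != 0))
  r <- lapply(co$spectra, nitrogen_index_lp)
  qc <- vapply(r, `[[`, logical(1), "qc_pass")
  rho <- cor(co$truth$age[qc], vapply(r, `[[`, numeric(1), "value")[qc],
             method = "spearman")
  expect_gt(rho, 0.8)
})

test_that("expression generator plants signed correlations and honest nulls", {
  ages <- seq(0.5, 8.5, length.out = 18)
  null_run <- simulate_expression(50, ages, n_planted_pos = 0,
                                  n_planted_neg = 0, seed = 5)
  expect_true(all(null_run$truth$planted_sign == 0))
  rs <- apply(null_run$counts, 1, cor, y = ages)
  expect_lt(median(abs(rs)), 0.25)
  planted <- simulate_expression(50, ages, n_planted_pos = 10,
                                 n_planted_neg = 10, rho = 0.8, seed = 5)
  r_pos <- apply(planted$counts[planted$truth$planted_sign == 1, ], 1,
                 cor, y = ages)
  r_neg <- apply(planted$counts[planted$truth$planted_sign == -1, ], 1,
                 cor, y = ages)
  expect_gt(median(r_pos), 0.5)
  expect_lt(median(r_neg), -0.5)
  expect_true(all(planted$counts >= 0))
})

test_that("hyperspectral pixels are the planted reference mixtures", {
  refs <- lco_reference_pair()
  # pure and half-half mixtures reproduce the reference geometry
  expect_equal(which.max(refs$ref_q), which.min(abs(refs$wavelengths - 500)))
  expect_equal(which.max(refs$ref_h), which.min(abs(refs$wavelengths - 580)))
  hs <- simulate_hyperspectral(4, ages = c(0.1, 0.4, 0.7, 0.95),
                               noise_sd = 0, seed = 8)
  i <- which(hs$a_q > 0.01, arr.ind = TRUE)[1, ]
  px <- hs$image[i[1], i[2], ]
  expect_equal(px, hs$a_q[i[1], i[2]] * refs$ref_q +
                 hs$a_h[i[1], i[2]] * refs$ref_h, tolerance = 1e-12)
})

test_that("older plaque cores carry a higher 500/580 ratio by construction", {
  hs <- simulate_hyperspectral(4, ages = c(0.1, 0.4, 0.7, 0.95),
                               noise_sd = 0, seed = 8)
  ratios <- vapply(seq_len(4), function(k) {
    m <- disc_mask(dim(hs$abeta)[1], dim(hs$abeta)[2],
                   hs$truth$x[k], hs$truth$y[k], hs$truth$sigma[k])
    core_ratio(m, hs$image, hs$refs$wavelengths)
  }, numeric(1))
  expect_true(all(diff(ratios[order(hs$truth$age)]) > 0))
})

test_that("IHC generator paints recoverable ring profiles with class ordering", {
  ihc <- simulate_ihc(classes = c("hq", "h", "none"), noise_sd = 0, seed = 1)
  rs <- remove_overlaps(lapply(ihc$masks, build_rings,
                               pixel_size = ihc$pixel_size))
  rm_ <- ring_means(ihc$channels$lamp1, rs)
  planted <- ihc$profiles$lamp1[cbind(ihc$classes[rm_$plaque], paste0("ring", rm_$ring))]
  expect_equal(rm_$mean_gray, unname(planted), tolerance = 1e-12)
  ring0 <- rm_$mean_gray[rm_$ring == 0]
  expect_true(ring0[1] > ring0[2] && ring0[2] > ring0[3])  # hq > h > none
})
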