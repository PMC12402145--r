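# Elemental compositions, exact masses and isotopologue patterns.

test_that("residue formulas sum correctly and termini add one water", {
  g <- composition_from_sequence("G")
  expect_equal(unclass(g)[c("C", "H", "N", "O")], c(C = 2, H = 5, N = 1, O = 2))
  gg <- composition_from_sequence("GG")
  expect_equal(unclass(gg)[c("C", "H", "N", "O")], c(C = 4, H = 8, N = 2, O = 3))
  ab <- abeta_comp()
  # backbone N (42) + Arg (3) + 3xHis (6) + 2xLys (2) + Gln (1) + Asn (1)
  expect_identical(unclass(ab)[["N"]], 42L + 3L + 6L + 2L + 1L + 1L)
})

test_that("unknown residues are rejected with their position", {
  expect_error(composition_from_sequence("GAZG"), "position 3")
  expect_error(composition_from_sequence("GAB"), "'B'")
})

test_that("monoisotopic m/z matches the instrument reference values", {
  ab <- abeta_comp()
  expect_equal(monoisotopic_mz(ab, 1), 4512.3, tolerance = 0.05 / 4512.3)
  expect_identical(round(monoisotopic_mz(ab, 1)), 4512)
  h2o <- c(C = 0, H = 2, N = 0, O = 1, S = 0)
  expect_equal(monoisotopic_mz(h2o, 1), 19.018, tolerance = 1e-4)
  expect_error(monoisotopic_mz(ab, 0), "charge")
})

test_that("two-nitrogen toy pattern is the binomial and natural q is the identity", {
  n2 <- c(C = 0, H = 0, N = 2, O = 0, S = 0)
  pat <- isotopologue_pattern(n2, enrichment_params(0.5))
  expect_equal(pat$abundances, c(0.25, 0.5, 0.25), tolerance = 1e-12)
  expect_equal(diff(pat$masses), rep(0.9970349, 2), tolerance = 1e-9)
  nat <- isotopologue_pattern(abeta_comp(), enrichment_params(0.00364))
  def <- isotopologue_pattern(abeta_comp())
  expect_equal(nat$abundances, def$abundances, tolerance = 1e-12)
})

test_that("patterns are normalized, 1 Da spaced, and anchored at the monoisotopic mass", {
  ab <- abeta_comp()
  for (q in c(0.00364, 0.1, 0.3)) {
    pat <- isotopologue_pattern(ab, enrichment_params(q), prune = 1e-10)
    expect_equal(sum(pat$abundances), 1, tolerance = 1e-9)
    expect_true(all(diff(pat$masses) > 0.99 & diff(pat$masses) < 1.01))
    if (pat$offsets[1] == 0) {
      expect_equal(pat$masses[1], monoisotopic_mz(ab, 1), tolerance = 1e-9)
    }
  }
})

test_that("centroid matches the closed-form per-element expectation", {
  ab <- abeta_comp()
  pat <- isotopologue_pattern(ab, prune = 1e-10)
  # independent expectation: sum over elements of n_e * E[extra mass/atom]
  expected_offset <-
    203 * 0.0107 * 1.0033548 +
    311 * 0.000115 * 1.0062767 +
    55 * 0.00364 * 0.9970349 +
    60 * (0.00038 * 1.0042169 + 0.00205 * 2.0042449) +
    1 * (0.0075 * 0.9993878 + 0.0429 * 1.9957959 + 0.0001 * 3.9950118)
  expect_equal(pattern_centroid(pat) - monoisotopic_mz(ab, 1),
               expected_offset, tolerance = 1e-3)
  # the natural envelope sits ~2.8 Da above the monoisotopic peak
  expect_equal(pattern_centroid(pat) - monoisotopic_mz(ab, 1), 2.8,
               tolerance = 0.05)
})

test_that("centroid shift with enrichment follows 55 * dq * 0.99703", {
  ab <- abeta_comp()
  nat <- pattern_centroid(isotopologue_pattern(ab))
  for (q in c(0.05, 0.20, 0.40)) {
    shift <- pattern_centroid(isotopologue_pattern(ab, enrichment_params(q))) - nat
    expect_equal(shift, 55 * (q - 0.00364) * 0.99703, tolerance = 0.01)
  }
  expect_equal(centroid_shift_15n(ab, 0.20), 10.77, tolerance = 0.01)
})

test_that("pattern_centroid handles trivial and degenerate inputs", {
  expect_equal(pattern_centroid(list(masses = 10, abundances = 1)), 10)
  expect_equal(pattern_centroid(list(masses = c(10, 12),
                                     abundances = c(0.5, 0.5))), 11)
  expect_error(pattern_centroid(list(masses = numeric(0),
                                     abundances = numeric(0))), "empty")
})

test_that("convolution agrees bin-by-bin with brute-force enumeration", {
  cases <- list(
    list(comp = c(C = 0, H = 0, N = 2, O = 0, S = 0), q = 0.5),
    list(comp = c(C = 2, H = 0, N = 2, O = 1, S = 1), q = 0.00364),
    list(comp = c(C = 2, H = 0, N = 2, O = 1, S = 1), q = 0.30),
    list(comp = c(C = 3, H = 2, N = 1, O = 0, S = 0), q = 0.15)
  )
  for (cs in cases) {
    pat <- isotopologue_pattern(cs$comp, enrichment_params(cs$q),
                                prune = 1e-30)
    oracle <- brute_force_pattern(cs$comp[cs$comp > 0], cs$q)
    shared <- intersect(pat$offsets, oracle$offset)
    expect_true(length(shared) >= length(oracle$offset) - 1)
    for (b in shared) {
      expect_equal(pat$abundances[match(b, pat$offsets)],
                   oracle$abundance[match(b, oracle$offset)],
                   tolerance = 1e-10)
    }
    # bin centroids match the enumerated conditional mean masses
    mono <- monoisotopic_mz(cs$comp, 1L)
    for (b in shared) {
      expect_equal(pat$masses[match(b, pat$offsets)] - mono,
                   oracle$mean_dmass[match(b, oracle$offset)],
                   tolerance = 1e-9)
    }
  }
})

test_that("theoretical 4/3 peak ratio behaves and increases with enrichment", {
  toy <- list(masses = 1:4, abundances = rep(0.25, 4), offsets = 0:3)
  expect_equal(theoretical_peak_ratio(toy, 4, 3), 1.0)
  n2 <- isotopologue_pattern(c(C = 0, H = 0, N = 2, O = 0, S = 0),
                             enrichment_params(0.5))
  expect_equal(theoretical_peak_ratio(n2, 2, 1), 2.0, tolerance = 1e-12)
  expect_error(theoretical_peak_ratio(n2, 9, 1), "missing")
  ab <- abeta_comp()
  qs <- seq(0.00364, 0.25, length.out = 8)
  ratios <- vapply(qs, function(q) {
    theoretical_peak_ratio(isotopologue_pattern(ab, enrichment_params(q)), 4, 3)
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})

test_that("patterns export as a two-column table", {
  tab <- pattern_as_table(isotopologue_pattern(abeta_comp()))
  expect_named(tab, c("mass", "abundance"))
  expect_equal(sum(tab$abundance), 1, tolerance = 1e-9)
})
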