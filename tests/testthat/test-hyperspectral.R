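# NNLS unmixing, maturity ratios, segmentation and plaque typing.

test_that("unmixing recovers exact mixtures and rejects collinear references", {
  refs <- lco_reference_pair()
  px <- array(refs$ref_q, dim = c(1, 1, 32))
  um <- linear_unmix(px, refs)
  expect_equal(um$a_q[1, 1], 1, tolerance = 1e-12)
  expect_equal(um$a_h[1, 1], 0, tolerance = 1e-12)
  mix <- array(0.3 * refs$ref_q + 0.7 * refs$ref_h, dim = c(1, 1, 32))
  um2 <- linear_unmix(mix, refs)
  expect_equal(c(um2$a_q[1, 1], um2$a_h[1, 1]), c(0.3, 0.7), tolerance = 1e-6)
  expect_equal(um2$residual[1, 1], 0, tolerance = 1e-9)
  bad <- list(ref_q = refs$ref_q, ref_h = 2 * refs$ref_q)
  expect_error(linear_unmix(mix, bad), "collinear")
})

test_that("unmixing abundances stay non-negative with bounded residuals", {
  refs <- lco_reference_pair()
  set.seed(4)
  img <- simulate_hyperspectral(4, noise_sd = 0.05, seed = 4)$image
  um <- linear_unmix(img, refs)
  expect_true(all(um$a_q >= 0))
  expect_true(all(um$a_h >= 0))
  pix_norm <- sqrt(apply(img^2, c(1, 2), sum))
  expect_true(all(um$residual <= pix_norm + 1e-9))
  # a pixel that is anti-correlated with q clamps a_q to zero
  anti <- array(pmax(refs$ref_h - 0.5 * refs$ref_q, 0), dim = c(1, 1, 32))
  um3 <- linear_unmix(anti, refs)
  expect_equal(um3$a_q[1, 1], 0)
  expect_gt(um3$a_h[1, 1], 0)
})

test_that("500/580 ratio uses nearest channels and flags zero denominators", {
  wl <- seq(450, 700, length.out = 32)
  expect_equal(ratio_500_580(rep(2, 32), wl), 1.0)
  refs <- lco_reference_pair()
  expect_lt(ratio_500_580(refs$ref_h, wl), 1)
  expect_gt(ratio_500_580(refs$ref_q, wl), 1)
  zero <- rep(0, 32)
  zero[which.min(abs(wl - 500))] <- 1
  expect_true(is.infinite(ratio_500_580(zero, wl)) ||
                is.nan(ratio_500_580(zero, wl)))
})

test_that("core ratio averages around the hottest in-mask pixel", {
  refs <- lco_reference_pair()
  h <- 21; w <- 21
  a_q <- matrix(0.1, h, w); a_q[5, 5] <- 1    # planted hot spot
  a_h <- matrix(1, h, w)
  img <- array(0, dim = c(h, w, 32))
  for (ch in 1:32) img[, , ch] <- a_q * refs$ref_q[ch] + a_h * refs$ref_h[ch]
  mask <- matrix(TRUE, h, w)
  full <- ratio_500_580(img, refs$wavelengths)
  expect_gt(core_ratio(mask, img, refs$wavelengths), mean(full))
  # uniform plaque: core ratio equals the pixel ratio everywhere
  a_q2 <- matrix(0.5, h, w)
  img2 <- array(0, dim = c(h, w, 32))
  for (ch in 1:32) img2[, , ch] <- a_q2 * refs$ref_q[ch] + a_h * refs$ref_h[ch]
  r2 <- ratio_500_580(img2, refs$wavelengths)[1, 1]
  expect_equal(core_ratio(mask, img2, refs$wavelengths), r2, tolerance = 1e-9)
  one_px <- matrix(FALSE, h, w); one_px[5, 5] <- TRUE
  expect_equal(core_ratio(one_px, img, refs$wavelengths),
               mean(ratio_500_580(img, refs$wavelengths)[3:7, 3:7][
                 outer(-2:2, -2:2, function(a, b) sqrt(a^2 + b^2)) <= 2]),
               tolerance = 1e-9)
})

test_that("segmentation recovers disc geometry and merges touching objects", {
  img <- matrix(0, 80, 80)
  img[disc_mask(80, 80, 40, 40, 10)] <- 1
  objs <- segment_plaques(img, pixel_size = 1, threshold = 0.5)
  expect_length(objs, 1)
  expect_equal(objs[[1]]$area_um2, pi * 100, tolerance = 0.05)
  expect_equal(unname(objs[[1]]$centroid_um), c(40, 40), tolerance = 0.5)
  expect_length(segment_plaques(matrix(0, 40, 40), 1), 0)
  two <- matrix(0, 60, 120)
  two[disc_mask(60, 120, 40, 30, 10) | disc_mask(60, 120, 59, 30, 10)] <- 1
  merged <- segment_plaques(two, 1, threshold = 0.5)
  expect_length(merged, 1)  # 8-connectivity merges touching discs
})

test_that("classification follows LCO positivity with the maturation ordering", {
  m <- matrix(TRUE, 4, 4)
  obj <- list(list(id = 1L, mask = m, centroid_um = c(x = 2, y = 2),
                   area_um2 = 16))
  zero <- matrix(0, 4, 4)
  high <- matrix(1, 4, 4)
  expect_equal(classify_plaques(obj, zero, zero, 0.1, 0.1)[[1]]$class,
               "Abeta+h-q-")
  expect_equal(classify_plaques(obj, zero, high, 0.1, 0.1)[[1]]$class,
               "Abeta+h+q-")
  expect_equal(classify_plaques(obj, high, high, 0.1, 0.1)[[1]]$class,
               "Abeta+h+q+")
  expect_equal(classify_plaques(obj, high, zero, 0.1, 0.1)[[1]]$class,
               "anomalous")
})

test_that("class area fractions partition area and count", {
  objs <- list(
    list(id = 1L, mask = NULL, centroid_um = c(0, 0), area_um2 = 100,
         class = "Abeta+h+q+"),
    list(id = 2L, mask = NULL, centroid_um = c(0, 0), area_um2 = 100,
         class = "Abeta+h-q-"))
  fr <- class_area_fractions(objs)
  expect_equal(sum(fr$area_fraction), 1, tolerance = 1e-9)
  expect_equal(sum(fr$count_fraction), 1, tolerance = 1e-9)
  expect_equal(fr$area_fraction, c(0.5, 0.5))
  single <- class_area_fractions(objs[1])
  expect_equal(single$area_fraction, 1)
})

test_that("planted area split is recovered within pixelation", {
  # plant the printed 41/24/35 area proportions via disc radii
  radii <- sqrt(c(41, 24, 35))  # areas scale with r^2
  img <- matrix(0, 120, 240)
  centers <- cbind(x = c(40, 120, 200), y = c(60, 60, 60))
  cls <- c("Abeta+h+q+", "Abeta+h+q-", "Abeta+h-q-")
  for (k in 1:3) img[disc_mask(120, 240, centers[k, 1], centers[k, 2],
                               radii[k] * 2)] <- 1
  objs <- segment_plaques(img, 1, threshold = 0.5)
  expect_length(objs, 3)
  # label by matching centroids to the planted classes
  for (i in seq_along(objs)) {
    k <- which.min(abs(centers[, "x"] - objs[[i]]$centroid_um[["x"]]))
    objs[[i]]$class <- cls[k]
  }
  fr <- class_area_fractions(objs)
  expect_equal(fr$area_fraction[match(cls, fr$class)],
               c(0.41, 0.24, 0.35), tolerance = 0.02)
})
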