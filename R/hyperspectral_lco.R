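# Linear unmixing of 32-channel LCO emission into q-FTAA / h-FTAA
# abundances, 500/580 nm maturity ratios, plaque segmentation and
# three-class typing (Abeta+h+q+, Abeta+h+q-, Abeta+h-q-).

#' Non-negative linear unmixing against a two-member reference pair
#'
#' Solves, per pixel, the non-negative least squares problem
#' s ~ a_q * ref_q + a_h * ref_h. For two components the NNLS solution is
#' closed form: the unconstrained 2x2 solution if it is non-negative,
#' otherwise the better of the two single-component fits.
#'
#' @param image H x W x C array (or C-vector for a single pixel).
#' @param refs A `reference_pair` (fields `ref_q`, `ref_h`).
#' @return List: `a_q`, `a_h` (H x W abundance maps), `residual` (H x W
#'   residual norms).
#' @export
linear_unmix <- function(image, refs) {
  rq <- refs$ref_q
  rh <- refs$ref_h
  gram <- matrix(c(sum(rq * rq), sum(rq * rh), sum(rq * rh), sum(rh * rh)), 2)
  if (abs(det(gram)) < 1e-12 * sum(rq^2) * sum(rh^2)) {
    stop("reference spectra are collinear")
  }
  if (is.null(dim(image)) || length(dim(image)) == 1) {
    image <- array(image, dim = c(1, 1, length(image)))
  }
  d <- dim(image)
  stopifnot(length(d) == 3, d[3] == length(rq))
  npx <- d[1] * d[2]
  S <- matrix(image, nrow = npx, ncol = d[3])  # pixels x channels
  bq <- as.numeric(S %*% rq)
  bh <- as.numeric(S %*% rh)
  inv <- solve(gram)
  aq <- inv[1, 1] * bq + inv[1, 2] * bh
  ah <- inv[2, 1] * bq + inv[2, 2] * bh
  # pixels where the unconstrained solution leaves the cone: clamp each
  # coefficient to zero in turn and keep the fit with lower residual
  bad <- which(aq < 0 | ah < 0)
  if (length(bad) > 0) {
    aq_only <- pmax(bq[bad] / sum(rq * rq), 0)
    ah_only <- pmax(bh[bad] / sum(rh * rh), 0)
    ss <- rowSums(S[bad, , drop = FALSE]^2)
    res_q <- ss - 2 * aq_only * bq[bad] + aq_only^2 * sum(rq * rq)
    res_h <- ss - 2 * ah_only * bh[bad] + ah_only^2 * sum(rh * rh)
    use_q <- res_q <= res_h
    aq[bad] <- ifelse(use_q, aq_only, 0)
    ah[bad] <- ifelse(use_q, 0, ah_only)
  }
  fitted_ss <- aq^2 * gram[1, 1] + 2 * aq * ah * gram[1, 2] + ah^2 * gram[2, 2]
  resid <- sqrt(pmax(rowSums(S^2) - 2 * (aq * bq + ah * bh) + fitted_ss, 0))
  list(a_q = matrix(aq, d[1], d[2]), a_h = matrix(ah, d[1], d[2]),
       residual = matrix(resid, d[1], d[2]))
}

#' 500/580 nm emission ratio
#'
#' Intensity at the channel nearest 500 nm divided by intensity at the
#' channel nearest 580 nm (no interpolation: discrete detector bins).
#'
#' @param x C-vector (single spectrum) or H x W x C array.
#' @param wavelengths Channel wavelength grid (nm), covering 500 and 580.
#' @return Scalar or H x W matrix; zero-denominator entries are `NaN`.
#' @export
ratio_500_580 <- function(x, wavelengths) {
  stopifnot(min(wavelengths) <= 500, max(wavelengths) >= 580)
  i500 <- which.min(abs(wavelengths - 500))
  i580 <- which.min(abs(wavelengths - 580))
  if (is.null(dim(x)) || length(dim(x)) == 1) {
    return(x[i500] / x[i580])
  }
  x[, , i500] / x[, , i580]
}

#' Core 500/580 ratio of a plaque
#'
#' Finds the in-mask pixel with the highest 500/580 ratio (the maturing
#' core) and averages the ratio over a small disc around it, clipped at the
#' image bounds.
#'
#' @param mask Logical H x W plaque mask (non-empty).
#' @param image H x W x C hyperspectral array.
#' @param wavelengths Channel wavelengths (nm).
#' @param disc_radius_px Averaging disc radius in pixels (default 2).
#' @return Mean core ratio (finite in-disc values only).
#' @export
core_ratio <- function(mask, image, wavelengths, disc_radius_px = 2) {
  mask <- mask > 0
  if (!any(mask)) stop("empty plaque mask")
  rmap <- ratio_500_580(image, wavelengths)
  rin <- rmap
  rin[!mask] <- -Inf
  rin[!is.finite(rin)] <- -Inf
  best <- which(rin == max(rin), arr.ind = TRUE)[1, ]
  h <- nrow(rmap); w <- ncol(rmap)
  rows <- max(1, best[1] - disc_radius_px):min(h, best[1] + disc_radius_px)
  cols <- max(1, best[2] - disc_radius_px):min(w, best[2] + disc_radius_px)
  sub <- rmap[rows, cols]
  dr <- outer(rows - best[1], cols - best[2],
              function(a, b) sqrt(a^2 + b^2))
  vals <- sub[dr <= disc_radius_px]
  mean(vals[is.finite(vals)])
}

#' Segment plaques on the amyloid channel
#'
#' Threshold (Otsu by default, or a fixed value), label connected components
#' (8-connectivity; touching objects merge), and filter by minimum area.
#'
#' @param abeta H x W amyloid channel.
#' @param pixel_size Micrometers per pixel.
#' @param threshold `"otsu"` or a numeric cutoff.
#' @param min_area_um2 Minimum object area in square micrometers
#'   (default 10).
#' @return List of plaque objects, each a list: `id`, `mask`, `centroid_um`,
#'   `area_um2`. Empty list for a blank image.
#' @export
segment_plaques <- function(abeta, pixel_size, threshold = "otsu",
                            min_area_um2 = 10) {
  stopifnot(is.numeric(pixel_size), pixel_size > 0)
  if (all(abeta == 0)) return(list())
  if (identical(threshold, "otsu")) {
    rng <- range(abeta)
    scaled <- (abeta - rng[1]) / diff(rng)
    threshold <- rng[1] + EBImage::otsu(scaled, range = c(0, 1)) * diff(rng)
  }
  bw <- abeta > threshold
  if (!any(bw)) return(list())
  lab <- EBImage::bwlabel(EBImage::Image(bw * 1))
  labm <- EBImage::imageData(lab)
  px_area <- pixel_size^2
  objs <- list()
  for (id in seq_len(max(labm))) {
    m <- labm == id
    area <- sum(m) * px_area
    if (area < min_area_um2) next
    ij <- which(m, arr.ind = TRUE)
    objs[[length(objs) + 1]] <- list(
      id = length(objs) + 1L, mask = m,
      centroid_um = c(x = mean(ij[, 2]) * pixel_size,
                      y = mean(ij[, 1]) * pixel_size),
      area_um2 = area)
  }
  objs
}

#' Classify plaques by LCO positivity
#'
#' Within each plaque mask, q+ iff mean q-FTAA abundance exceeds `q_thresh`
#' and h+ iff mean h-FTAA abundance exceeds `h_thresh`. Labels follow the
#' amyloid maturation ordering: `Abeta+h+q+`, `Abeta+h+q-`, `Abeta+h-q-`;
#' the combination h-q+ violates that ordering and is flagged `anomalous`.
#'
#' @param objects Plaque list from [segment_plaques()].
#' @param a_q,a_h Abundance maps from [linear_unmix()].
#' @param q_thresh,h_thresh Non-negative positivity cutoffs.
#' @return The objects with `$class`, `$mean_a_q`, `$mean_a_h` added.
#' @export
classify_plaques <- function(objects, a_q, a_h, q_thresh, h_thresh) {
  stopifnot(q_thresh >= 0, h_thresh >= 0)
  lapply(objects, function(ob) {
    mq <- mean(a_q[ob$mask])
    mh <- mean(a_h[ob$mask])
    qpos <- mq > q_thresh
    hpos <- mh > h_thresh
    ob$mean_a_q <- mq
    ob$mean_a_h <- mh
    ob$class <- if (hpos && qpos) "Abeta+h+q+"
      else if (hpos) "Abeta+h+q-"
      else if (!qpos) "Abeta+h-q-"
      else "anomalous"
    ob
  })
}

#' Per-class area and count fractions
#'
#' @param objects Classified plaque list (>= 1 object).
#' @return data.frame: class, n, area_um2, area_fraction, count_fraction;
#'   both fraction columns sum to 1.
#' @export
class_area_fractions <- function(objects) {
  stopifnot(length(objects) >= 1)
  cls <- vapply(objects, `[[`, character(1), "class")
  area <- vapply(objects, `[[`, numeric(1), "area_um2")
  agg <- stats::aggregate(data.frame(n = 1, area_um2 = area),
                          by = list(class = cls), FUN = sum)
  agg$area_fraction <- agg$area_um2 / sum(agg$area_um2)
  agg$count_fraction <- agg$n / sum(agg$n)
  agg
}
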