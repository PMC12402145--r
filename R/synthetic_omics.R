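# Seeded generators for plaque-age-correlated expression matrices,
# 32-channel LCO emission images and radial IHC channel images.

#' Simulate an AOI-level count matrix with planted age correlations
#'
#' Planted genes have a latent Gaussian signal with Pearson correlation
#' +/- rho to plaque age; null genes have none. Latents are mapped through a
#' log link to negative-binomial counts with lognormal AOI size factors.
#'
#' @param n_genes Total genes.
#' @param ages Per-AOI plaque age (length = number of AOIs).
#' @param n_planted_pos,n_planted_neg Numbers of genes planted with positive
#'   / negative age correlation.
#' @param rho Planted latent correlation magnitude (|rho| < 1).
#' @param dispersion Negative-binomial size parameter (default 20).
#' @param base_log_mu Log mean count (default log(200)).
#' @param link_scale Log-fold-change per latent SD (default 0.5).
#' @param seed Integer seed.
#' @return List with `counts` (genes x AOIs integer matrix, dimnames set)
#'   and `truth` (data.frame: gene, planted_sign in {-1, 0, 1}, rho).
#' @export
simulate_expression <- function(n_genes = 200L, ages,
                                n_planted_pos = 10L, n_planted_neg = 10L,
                                rho = 0.8, dispersion = 20,
                                base_log_mu = log(200), link_scale = 0.5,
                                seed = 1L) {
  stopifnot(abs(rho) < 1, n_planted_pos + n_planted_neg <= n_genes,
            length(ages) >= 4)
  n_aoi <- length(ages)
  signs <- c(rep(1L, n_planted_pos), rep(-1L, n_planted_neg),
             rep(0L, n_genes - n_planted_pos - n_planted_neg))
  a_std <- if (stats::sd(ages) > 0) (ages - mean(ages)) / stats::sd(ages)
           else rep(0, n_aoi)
  .with_seed(seed, {
    size_factors <- exp(stats::rnorm(n_aoi, 0, 0.1))
    counts <- matrix(0L, n_genes, n_aoi)
    for (g in seq_len(n_genes)) {
      eps <- stats::rnorm(n_aoi)
      z <- if (signs[g] == 0L) eps else
        signs[g] * rho * a_std + sqrt(1 - rho^2) * eps
      mu <- exp(base_log_mu + link_scale * z) * size_factors
      counts[g, ] <- stats::rnbinom(n_aoi, mu = mu, size = dispersion)
    }
    dimnames(counts) <- list(sprintf("gene_%03d", seq_len(n_genes)),
                             sprintf("aoi_%02d", seq_len(n_aoi)))
    list(counts = counts,
         truth = data.frame(gene = rownames(counts), planted_sign = signs,
                            rho = ifelse(signs == 0L, 0, rho)))
  })
}

#' Gaussian LCO reference emission spectra
#'
#' q-FTAA-like and h-FTAA-like references modeled as Gaussians over a
#' 450-700 nm 32-channel grid, peaking near 500 and 580 nm. Measured
#' references can be substituted via [read_reference_spectra()].
#'
#' @param n_channels Number of detector channels (default 32).
#' @param range_nm Wavelength range (default c(450, 700)).
#' @return List of class `reference_pair`: `wavelengths`, `ref_q`, `ref_h`.
#' @export
lco_reference_pair <- function(n_channels = 32L, range_nm = c(450, 700)) {
  wl <- seq(range_nm[1], range_nm[2], length.out = n_channels)
  ref_q <- exp(-(wl - 500)^2 / (2 * 25^2))
  ref_h <- exp(-(wl - 580)^2 / (2 * 30^2))
  structure(list(wavelengths = wl, ref_q = ref_q, ref_h = ref_h),
            class = "reference_pair")
}

# Radial Gaussian blob amplitude on a pixel grid.
.blob <- function(height, width, cx, cy, sigma) {
  xs <- matrix(rep(seq_len(width), each = height), height, width)
  ys <- matrix(rep(seq_len(height), width), height, width)
  exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * sigma^2))
}

# Non-overlapping plaque centers on a jittered grid.
.place_centers <- function(n, height, width, margin) {
  per_row <- ceiling(sqrt(n))
  gx <- seq(margin, width - margin, length.out = per_row)
  gy <- seq(margin, height - margin, length.out = ceiling(n / per_row))
  grid <- expand.grid(x = gx, y = gy)
  grid[seq_len(n), , drop = FALSE]
}

#' Simulate a 32-channel hyperspectral LCO image
#'
#' Plaques are radial blobs whose per-pixel spectrum is a non-negative
#' mixture a_q * ref_q + a_h * ref_h plus Gaussian noise. The q-FTAA
#' fraction at the plaque core increases with plaque age (mature, compact
#' amyloid), so older cores carry a higher 500/580 nm ratio.
#'
#' @param n_plaques Number of plaques.
#' @param ages Per-plaque age in [0, 1] (default uniform draws).
#' @param classes Optional per-plaque class in `c("hq", "h", "none")`
#'   (A-beta+h+q+, A-beta+h+q-, A-beta+h-q-); default all `"hq"`.
#' @param radii Optional per-plaque blob sigma in pixels (default U(4, 8)).
#' @param height,width Image size in pixels.
#' @param pixel_size Pixel edge in micrometers.
#' @param noise_sd Gaussian channel noise sd (absolute; signal amplitude 1).
#' @param refs A [lco_reference_pair()].
#' @param seed Integer seed.
#' @return List: `image` (H x W x C array), `abeta` (H x W amyloid channel),
#'   `a_q`, `a_h` (true abundance maps), `refs`, `pixel_size`, `truth`
#'   (data.frame: plaque, x, y, sigma, age, class).
#' @export
simulate_hyperspectral <- function(n_plaques = 6L, ages = NULL, classes = NULL,
                                   radii = NULL, height = 160L, width = 160L,
                                   pixel_size = 1, noise_sd = 0.02,
                                   refs = lco_reference_pair(), seed = 1L) {
  .with_seed(seed, {
    if (is.null(ages)) ages <- stats::runif(n_plaques)
    if (is.null(classes)) classes <- rep("hq", n_plaques)
    if (is.null(radii)) radii <- stats::runif(n_plaques, 4, 8)
    stopifnot(all(classes %in% c("hq", "h", "none")),
              length(ages) == n_plaques, length(radii) == n_plaques)
    centers <- .place_centers(n_plaques, height, width,
                              margin = max(radii) * 3 + 2)
    a_q <- matrix(0, height, width)
    a_h <- matrix(0, height, width)
    abeta <- matrix(0, height, width)
    for (i in seq_len(n_plaques)) {
      f <- .blob(height, width, centers$x[i], centers$y[i], radii[i])
      core <- .blob(height, width, centers$x[i], centers$y[i], radii[i] / 2)
      lv <- switch(classes[i],
                   hq = c(q_base = 0.25, q_core = 0.75, h = 0.7),
                   h = c(q_base = 0.01, q_core = 0, h = 0.7),
                   none = c(q_base = 0.01, q_core = 0, h = 0.01))
      a_q <- a_q + f * (lv[["q_base"]] + lv[["q_core"]] * ages[i] * core)
      a_h <- a_h + f * lv[["h"]]
      abeta <- abeta + f
    }
    nc <- length(refs$wavelengths)
    img <- array(0, dim = c(height, width, nc))
    for (ch in seq_len(nc)) {
      img[, , ch] <- a_q * refs$ref_q[ch] + a_h * refs$ref_h[ch] +
        if (noise_sd > 0) matrix(stats::rnorm(height * width, 0, noise_sd),
                                 height, width) else 0
    }
    img <- pmax(img, 0)
    abeta_noisy <- pmax(abeta + if (noise_sd > 0)
      matrix(stats::rnorm(height * width, 0, noise_sd), height, width) else 0, 0)
    list(image = img, abeta = abeta_noisy, a_q = a_q, a_h = a_h, refs = refs,
         pixel_size = pixel_size,
         truth = data.frame(plaque = seq_len(n_plaques), x = centers$x,
                            y = centers$y, sigma = radii, age = ages,
                            class = classes))
  })
}

#' Default radial intensity profiles per plaque class
#'
#' Mean gray values on rings 0 (plaque), 1 (0-10 um), 2 (10-20 um),
#' 3 (20-30 um). The LAMP1-like marker (dystrophic neurites) decreases with
#' distance and is strongest around mature (h+q+) plaques; the HOMER1-like
#' marker (postsynaptic density) dips at the plaque, deepest for mature
#' plaques.
#'
#' @return List of two class-by-ring matrices: `lamp1`, `homer1`.
#' @export
default_ring_profiles <- function() {
  classes <- c("hq", "h", "none")
  lamp1 <- rbind(hq = c(200, 150, 110, 100),
                 h = c(160, 130, 105, 100),
                 none = c(120, 110, 102, 100))
  homer1 <- rbind(hq = c(50, 75, 95, 100),
                  h = c(65, 85, 97, 100),
                  none = c(85, 95, 100, 100))
  colnames(lamp1) <- colnames(homer1) <- paste0("ring", 0:3)
  list(lamp1 = lamp1, homer1 = homer1)
}

#' Simulate IHC channel images around classified plaques
#'
#' Disc plaques placed without mutual ring overlap (unless
#' `min_separation_um` forces it); each channel is piecewise constant on the
#' plaque's concentric rings at the class profile value, plus Gaussian noise.
#'
#' @param classes Per-plaque class in `c("hq", "h", "none")`.
#' @param radii_um Per-plaque disc radius in micrometers (default 8).
#' @param profiles List of class-by-ring matrices (default
#'   [default_ring_profiles()]); ring width fixed by `increment_um`.
#' @param increment_um Ring width (default 10) and `max_um` outer limit
#'   (default 30).
#' @param max_um Outer ring limit.
#' @param pixel_size Micrometers per pixel (default 1).
#' @param noise_sd Gaussian noise sd in gray values (0 for noiseless).
#' @param background Gray value far from any plaque (default 100).
#' @param seed Integer seed.
#' @return List: `channels` (named list of H x W matrices), `masks` (list of
#'   logical plaque masks), `classes`, `pixel_size`, `profiles`, `truth`.
#' @export
simulate_ihc <- function(classes = c("hq", "h", "none"),
                         radii_um = NULL, profiles = default_ring_profiles(),
                         increment_um = 10, max_um = 30, pixel_size = 1,
                         noise_sd = 0, background = 100, seed = 1L) {
  n <- length(classes)
  if (is.null(radii_um)) radii_um <- rep(8, n)
  stopifnot(all(classes %in% rownames(profiles[[1]])),
            length(radii_um) == n)
  reach_px <- (max(radii_um) + max_um) / pixel_size
  cell <- ceiling(2 * reach_px + 4)
  per_row <- ceiling(sqrt(n))
  height <- width <- cell * per_row
  centers <- data.frame(
    x = (((seq_len(n) - 1L) %% per_row) + 0.5) * cell,
    y = (((seq_len(n) - 1L) %/% per_row) + 0.5) * cell)
  xs <- matrix(rep(seq_len(width), each = height), height, width)
  ys <- matrix(rep(seq_len(height), width), height, width)
  n_rings <- max_um / increment_um
  masks <- vector("list", n)
  channels <- lapply(profiles, function(pr) matrix(background, height, width))
  for (i in seq_len(n)) {
    d_px <- sqrt((xs - centers$x[i])^2 + (ys - centers$y[i])^2)
    masks[[i]] <- d_px <= radii_um[i] / pixel_size
    # paint on the same Euclidean-distance-transform shells the ring
    # analysis measures, so noiseless profiles are recovered exactly
    d_um <- .edt_to_mask(masks[[i]]) * pixel_size
    for (ch in names(profiles)) {
      pr <- profiles[[ch]][classes[i], ]
      for (k in 0:n_rings) {
        ring_px <- if (k == 0) masks[[i]] else
          d_um > (k - 1) * increment_um & d_um <= k * increment_um
        channels[[ch]][ring_px] <- pr[k + 1]
      }
    }
  }
  if (noise_sd > 0) {
    channels <- .with_seed(seed, lapply(channels, function(m)
      m + matrix(stats::rnorm(length(m), 0, noise_sd), nrow(m), ncol(m))))
  }
  list(channels = channels, masks = masks, classes = classes,
       pixel_size = pixel_size, profiles = profiles,
       truth = data.frame(plaque = seq_len(n), class = classes,
                          x = centers$x, y = centers$y, radius_um = radii_um))
}
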