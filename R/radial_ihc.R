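# Concentric-ring quantification of marker intensity around classified
# plaques: std-projection, Euclidean-distance-transform shells at 10-um
# increments to 30 um, symmetric overlap removal, per-ring means and
# class/image/animal aggregation.

#' Standard-deviation z-projection
#'
#' Per-pixel standard deviation across planes (population form, divisor n).
#'
#' @param stack H x W x Z array or list of H x W matrices (>= 2 planes;
#'   a single plane is returned unchanged with a warning).
#' @return H x W matrix.
#' @export
project_zstack <- function(stack) {
  if (is.list(stack)) stack <- simplify2array(stack)
  if (length(dim(stack)) == 2 || dim(stack)[3] == 1) {
    warning("single-plane stack: projection is the identity")
    return(if (length(dim(stack)) == 3) stack[, , 1] else stack)
  }
  nz <- dim(stack)[3]
  mu <- apply(stack, c(1, 2), mean)
  ss <- apply(stack^2, c(1, 2), mean)
  sqrt(pmax(ss - mu^2, 0))
}

# Exact Euclidean distance (in pixels) from every pixel to the nearest TRUE
# pixel of `mask`, via the two-pass Felzenszwalb-Huttenlocher transform.
.edt_to_mask <- function(mask) {
  inf <- .Machine$double.xmax / 4
  f <- matrix(ifelse(mask, 0, inf), nrow(mask), ncol(mask))
  dt1 <- function(v) {
    n <- length(v)
    if (n == 1) return(v)
    d <- numeric(n)
    vx <- integer(n)  # parabola locations
    z <- numeric(n + 1)
    k <- 1L
    vx[1] <- 1L
    z[1] <- -Inf
    z[2] <- Inf
    for (q in 2:n) {
      repeat {
        p <- vx[k]
        s <- ((v[q] + q^2) - (v[p] + p^2)) / (2 * q - 2 * p)
        if (s <= z[k]) {
          k <- k - 1L
        } else {
          k <- k + 1L
          vx[k] <- q
          z[k] <- s
          z[k + 1] <- Inf
          break
        }
      }
    }
    k <- 1L
    for (q in 1:n) {
      while (z[k + 1] < q) k <- k + 1L
      d[q] <- (q - vx[k])^2 + v[vx[k]]
    }
    d
  }
  g <- apply(f, 2, dt1)          # columns: squared distance along rows
  d2 <- t(apply(g, 1, dt1))      # rows
  sqrt(d2)
}

#' Concentric ring masks around a plaque
#'
#' Ring 0 is the plaque mask itself; ring k is the Euclidean
#' distance-transform shell (k-1)*increment < d <= k*increment (micrometers
#' from the mask edge), up to `max_um`.
#'
#' @param mask Logical H x W plaque mask (non-empty).
#' @param pixel_size Micrometers per pixel (required, no default).
#' @param increment_um Ring width (default 10).
#' @param max_um Outer limit, a multiple of the increment (default 30).
#' @return List of class `ring_set`: `rings` (list of logical masks, ring0
#'   first), `increment_um`, `max_um`, `clipped` (mask or outer ring touches
#'   the image border).
#' @export
build_rings <- function(mask, pixel_size, increment_um = 10, max_um = 30) {
  stopifnot(!missing(pixel_size), pixel_size > 0, increment_um > 0,
            abs(max_um / increment_um - round(max_um / increment_um)) < 1e-9)
  mask <- mask > 0
  if (!any(mask)) stop("empty plaque mask")
  d_um <- .edt_to_mask(mask) * pixel_size
  n_rings <- round(max_um / increment_um)
  rings <- vector("list", n_rings + 1L)
  rings[[1]] <- mask
  for (k in seq_len(n_rings)) {
    rings[[k + 1]] <- d_um > (k - 1) * increment_um & d_um <= k * increment_um
  }
  h <- nrow(mask); w <- ncol(mask)
  member <- Reduce(`|`, rings)
  clipped <- any(member[1, ]) || any(member[h, ]) ||
    any(member[, 1]) || any(member[, w])
  structure(list(rings = rings, increment_um = increment_um,
                 max_um = max_um, clipped = clipped, pixel_size = pixel_size),
            class = "ring_set")
}

#' Remove contested pixels across plaques' ring systems
#'
#' Any pixel belonging to two or more plaques' ring systems (including other
#' plaques' ring-0 masks) is excluded from every ring — symmetric removal,
#' so neither plaque keeps a contested pixel.
#'
#' @param ring_sets List of `ring_set` objects over the same image.
#' @return The ring sets with contested pixels removed from all rings.
#' @export
remove_overlaps <- function(ring_sets) {
  stopifnot(length(ring_sets) >= 1)
  dims <- dim(ring_sets[[1]]$rings[[1]])
  count <- matrix(0L, dims[1], dims[2])
  for (rs in ring_sets) {
    member <- Reduce(`|`, rs$rings)
    count <- count + member
  }
  contested <- count >= 2L
  lapply(ring_sets, function(rs) {
    rs$rings <- lapply(rs$rings, function(r) r & !contested)
    rs
  })
}

#' Mean intensity per ring
#'
#' @param image H x W intensity matrix (same shape as the masks).
#' @param ring_sets List of `ring_set` objects (post overlap removal).
#' @param ids Optional plaque ids (default sequence).
#' @return data.frame: plaque, ring (0-based), mean_gray (NA for empty
#'   rings), n_pixels.
#' @export
ring_means <- function(image, ring_sets, ids = NULL) {
  if (inherits(ring_sets, "ring_set")) ring_sets <- list(ring_sets)
  if (is.null(ids)) ids <- seq_along(ring_sets)
  stopifnot(identical(dim(image), dim(ring_sets[[1]]$rings[[1]])))
  rows <- list()
  for (i in seq_along(ring_sets)) {
    for (k in seq_along(ring_sets[[i]]$rings)) {
      r <- ring_sets[[i]]$rings[[k]]
      n <- sum(r)
      rows[[length(rows) + 1]] <- data.frame(
        plaque = ids[i], ring = k - 1L,
        mean_gray = if (n > 0) mean(image[r]) else NA_real_,
        n_pixels = n)
    }
  }
  do.call(rbind, rows)
}

#' Aggregate ring profiles by plaque type, image and animal
#'
#' Means over plaques within (class, image, ring), then over images within
#' (class, animal, ring). Per-group values more than `sd_cut` standard
#' deviations from the group mean are excluded first (toggle with
#' `exclude_outliers`). Empty rings (NA means) are dropped.
#'
#' @param profiles data.frame from [ring_means()] plus columns `class`,
#'   `image`, `animal`.
#' @param exclude_outliers Apply the > `sd_cut` SD exclusion (default TRUE).
#' @param sd_cut SD multiple for exclusion (default 2).
#' @return List: `by_image` (class x image x ring means with plaque counts),
#'   `by_animal` (class x animal x ring means with image counts).
#' @export
aggregate_profiles <- function(profiles, exclude_outliers = TRUE, sd_cut = 2) {
  needed <- c("class", "image", "animal", "ring", "mean_gray")
  if (!all(needed %in% names(profiles))) {
    stop("profiles must carry columns: ", paste(needed, collapse = ", "))
  }
  profiles <- profiles[!is.na(profiles$mean_gray), , drop = FALSE]
  if (exclude_outliers) {
    grp <- interaction(profiles$class, profiles$image, profiles$ring,
                       drop = TRUE)
    keep <- unlist(lapply(split(seq_len(nrow(profiles)), grp), function(ix) {
      v <- profiles$mean_gray[ix]
      if (length(v) < 3 || stats::sd(v) == 0) return(ix)
      ix[abs(v - mean(v)) <= sd_cut * stats::sd(v)]
    }))
    profiles <- profiles[sort(keep), , drop = FALSE]
  }
  by_image <- stats::aggregate(
    mean_gray ~ class + image + animal + ring, data = profiles, FUN = mean)
  n_plq <- stats::aggregate(
    mean_gray ~ class + image + animal + ring, data = profiles, FUN = length)
  by_image$n_plaques <- n_plq$mean_gray
  by_animal <- stats::aggregate(
    mean_gray ~ class + animal + ring, data = by_image, FUN = mean)
  n_img <- stats::aggregate(
    mean_gray ~ class + animal + ring, data = by_image, FUN = length)
  by_animal$n_images <- n_img$mean_gray
  list(by_image = by_image[order(by_image$class, by_image$image,
                                 by_image$ring), ],
       by_animal = by_animal[order(by_animal$class, by_animal$animal,
                                   by_animal$ring), ])
}

#' Correlate synaptic marker intensity with amyloid maturity
#'
#' Pearson correlation of per-plaque mean HOMER1-like intensity with the
#' per-plaque core q/h (500/580) ratio, per animal and pooled.
#'
#' @param intensity Per-plaque mean intensity.
#' @param maturity Per-plaque core ratio (same length, n >= 4).
#' @param animal Optional per-plaque animal labels for per-animal results.
#' @return data.frame: animal ("pooled" row always present), n, pearson_r,
#'   p_two_sided (NA with `undefined = TRUE` for zero-variance groups).
#' @export
homer_vs_maturity <- function(intensity, maturity, animal = NULL) {
  stopifnot(length(intensity) == length(maturity), length(intensity) >= 4)
  one <- function(x, y, label) {
    if (length(x) < 4 || stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(data.frame(animal = label, n = length(x), pearson_r = NA_real_,
                        p_two_sided = NA_real_, undefined = TRUE))
    }
    ct <- stats::cor.test(x, y)
    data.frame(animal = label, n = length(x),
               pearson_r = unname(ct$estimate), p_two_sided = ct$p.value,
               undefined = FALSE)
  }
  out <- one(intensity, maturity, "pooled")
  if (!is.null(animal)) {
    per <- lapply(split(seq_along(animal), animal), function(ix) {
      one(intensity[ix], maturity[ix], as.character(animal[ix][1]))
    })
    out <- rbind(out, do.call(rbind, per))
  }
  rownames(out) <- NULL
  out
}
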