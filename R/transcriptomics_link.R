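# Linking plaque age (nitrogen index) to single-plaque gene expression.

#' Quantile-normalize a genes x AOIs count matrix
#'
#' Forces every AOI column to share the same empirical distribution (the
#' mean of per-rank values across columns); ties receive the mean of their
#' spanned rank values. Delegates to limma's quantile engine.
#'
#' @param mat Numeric genes x AOIs matrix with >= 2 columns (a single column
#'   is returned unchanged with a warning).
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) {
    warning("single-column matrix: quantile normalization is the identity")
    return(mat)
  }
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Gene-wise Pearson correlation with plaque age
#'
#' Correlates each gene's (quantile-normalized) expression with the per-AOI
#' nitrogen index. Under the pulse-chase design a higher index marks an
#' older plaque (direct axis); under pulse-only the label marks recent
#' deposition, so the age axis is inverted before reporting.
#'
#' @param mat Genes x AOIs matrix (QC-passing AOIs only).
#' @param indices Per-AOI nitrogen-index values (length = ncol(mat)).
#' @param design `"pulse_chase"` (direct) or `"pulse_only"` (inverted axis).
#' @return data.frame: gene, pearson_r, p_two_sided, direction
#'   (positive/negative/ns), zero_variance flag.
#' @export
correlate_gene_age <- function(mat, indices,
                               design = c("pulse_chase", "pulse_only")) {
  design <- match.arg(design)
  mat <- as.matrix(mat)
  stopifnot(length(indices) == ncol(mat), ncol(mat) >= 4)
  age_axis <- if (design == "pulse_only") -indices else indices
  res <- lapply(seq_len(nrow(mat)), function(g) {
    y <- mat[g, ]
    if (stats::sd(y) == 0 || stats::sd(age_axis) == 0) {
      return(data.frame(pearson_r = NA_real_, p_two_sided = NA_real_,
                        zero_variance = TRUE))
    }
    ct <- stats::cor.test(age_axis, y, method = "pearson",
                          alternative = "two.sided")
    data.frame(pearson_r = unname(ct$estimate), p_two_sided = ct$p.value,
               zero_variance = FALSE)
  })
  out <- do.call(rbind, res)
  out$gene <- if (!is.null(rownames(mat))) rownames(mat) else
    sprintf("gene_%03d", seq_len(nrow(mat)))
  out$direction <- "ns"
  sig <- !out$zero_variance & out$p_two_sided < 0.05
  out$direction[sig & out$pearson_r > 0] <- "positive"
  out$direction[sig & out$pearson_r < 0] <- "negative"
  out[, c("gene", "pearson_r", "p_two_sided", "direction", "zero_variance")]
}

#' Split correlation results into volcano gene lists
#'
#' Partition at the uncorrected (non-FDR-adjusted) significance cutoff.
#'
#' @param results Output of [correlate_gene_age()].
#' @param p_cut Two-sided p cutoff (default 0.05).
#' @return List: `positive`, `negative` (gene id vectors), `ns` (the rest).
#' @export
volcano_split <- function(results, p_cut = 0.05) {
  stopifnot(p_cut > 0, p_cut < 1)
  if (nrow(results) == 0) return(list(positive = character(0),
                                      negative = character(0),
                                      ns = character(0)))
  ok <- !is.na(results$p_two_sided) & results$p_two_sided < p_cut
  list(positive = results$gene[ok & results$pearson_r > 0],
       negative = results$gene[ok & results$pearson_r < 0],
       ns = results$gene[!(ok & results$pearson_r != 0)])
}

#' Over-representation analysis by one-sided Fisher's exact test
#'
#' For each gene set, tests enrichment of the query list against the
#' background (all measured genes) on the 2x2 table, with Benjamini-Hochberg
#' correction across tested sets.
#'
#' @param gene_list Query genes (subset of background).
#' @param gene_sets Named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param background All measured gene ids.
#' @param p_cut,q_cut Reporting cutoffs (defaults 0.05 and 0.05).
#' @return data.frame: set, overlap, set_size, list_size, p, q, enriched
#'   (logical, p < p_cut & q < q_cut). Sets with no background overlap are
#'   skipped (attribute `"skipped"` lists them).
#' @export
ora_fisher <- function(gene_list, gene_sets, background,
                       p_cut = 0.05, q_cut = 0.05) {
  stopifnot(all(gene_list %in% background))
  gene_list <- unique(gene_list)
  background <- unique(background)
  in_bg <- lapply(gene_sets, intersect, background)
  skipped <- names(gene_sets)[lengths(in_bg) == 0]
  keep <- lengths(in_bg) > 0
  sets <- in_bg[keep]
  if (length(sets) == 0) {
    out <- data.frame(set = character(0), overlap = integer(0),
                      set_size = integer(0), list_size = integer(0),
                      p = numeric(0), q = numeric(0), enriched = logical(0))
    attr(out, "skipped") <- skipped
    return(out)
  }
  n_list <- length(gene_list)
  n_bg <- length(background)
  rows <- lapply(names(sets), function(nm) {
    s <- sets[[nm]]
    a <- length(intersect(gene_list, s))
    b <- n_list - a
    c_ <- length(s) - a
    d <- n_bg - n_list - c_
    data.frame(set = nm, overlap = a, set_size = length(s),
               list_size = n_list,
               p = fisher_exact_greater(a, b, c_, d))
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$enriched <- out$p < p_cut & out$q < q_cut
  attr(out, "skipped") <- skipped
  out[order(out$p), ]
}

#' Correlate nitrogen index with AOI covariates
#'
#' Checks that the index is not driven by AOI size, cell count or astrocyte
#' (GFAP) area fraction.
#'
#' @param metadata data.frame with columns `aoi_area`, `cell_count`,
#'   `gfap_area_fraction` (one row per AOI).
#' @param indices Per-AOI nitrogen-index values.
#' @return data.frame: covariate, pearson_r, p_two_sided, undefined flag
#'   (constant covariate).
#' @export
covariate_check <- function(metadata, indices) {
  needed <- c("aoi_area", "cell_count", "gfap_area_fraction")
  missing_cols <- setdiff(needed, names(metadata))
  if (length(missing_cols) > 0) {
    stop("missing covariate column(s): ", paste(missing_cols, collapse = ", "))
  }
  stopifnot(nrow(metadata) == length(indices), length(indices) >= 4)
  rows <- lapply(needed, function(cv) {
    x <- metadata[[cv]]
    if (stats::sd(x) == 0) {
      return(data.frame(covariate = cv, pearson_r = NA_real_,
                        p_two_sided = NA_real_, undefined = TRUE))
    }
    ct <- stats::cor.test(indices, x)
    data.frame(covariate = cv, pearson_r = unname(ct$estimate),
               p_two_sided = ct$p.value, undefined = FALSE)
  })
  do.call(rbind, rows)
}

#' GFAP-positive area fraction of an AOI
#'
#' Thresholded-positive pixel count divided by AOI mask pixel count; a
#' uniform numeric threshold should be applied across all images.
#'
#' @param image Numeric matrix (channel image).
#' @param mask Logical matrix, the AOI (must be non-empty).
#' @param threshold Numeric cutoff, or `"otsu"` for Otsu's method on the
#'   in-mask intensities (rescaled to [0, 1]).
#' @return Fraction in [0, 1].
#' @export
gfap_area_fraction <- function(image, mask, threshold = "otsu") {
  stopifnot(identical(dim(image), dim(mask)))
  mask <- mask > 0
  if (!any(mask)) stop("empty AOI mask")
  vals <- image[mask]
  if (identical(threshold, "otsu")) {
    rng <- range(vals)
    if (diff(rng) == 0) return(0)
    scaled <- (vals - rng[1]) / diff(rng)
    thr_s <- EBImage::otsu(matrix(scaled, nrow = 1), range = c(0, 1))
    threshold <- rng[1] + thr_s * diff(rng)
  }
  mean(vals > threshold)
}

#' Iterative two-sided Grubbs outlier test
#'
#' Repeatedly removes the most extreme value while the Grubbs statistic
#' G = max|x - mean| / sd exceeds the t-based critical value at `alpha`.
#'
#' @param values Numeric vector (n >= 3).
#' @param alpha Significance level per iteration (default 0.01).
#' @return Integer indices (into the original vector) of flagged outliers.
#' @export
grubbs_outlier <- function(values, alpha = 0.01) {
  n0 <- length(values)
  if (n0 < 3) stop("Grubbs test requires at least 3 values")
  idx <- seq_len(n0)
  flagged <- integer(0)
  repeat {
    n <- length(values)
    if (n < 3) break
    s <- stats::sd(values)
    if (s == 0) break
    dev <- abs(values - mean(values))
    g <- max(dev) / s
    tcrit <- stats::qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)
    gcrit <- ((n - 1) / sqrt(n)) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
    if (g <= gcrit) break
    worst <- which.max(dev)
    flagged <- c(flagged, idx[worst])
    values <- values[-worst]
    idx <- idx[-worst]
  }
  sort(flagged)
}

#' Drop genes with low geometric-mean counts
#'
#' @param counts Genes x AOIs matrix.
#' @param floor Geometric-mean floor; genes below it are removed
#'   (default 1).
#' @return Filtered matrix.
#' @export
filter_low_counts <- function(counts, floor = 1) {
  gm <- exp(rowMeans(log(counts + 0.5)))
  counts[gm >= floor, , drop = FALSE]
}
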