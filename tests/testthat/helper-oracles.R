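# Independent oracles used across tests. Constants are restated here on
# purpose so the oracles do not share code with the implementation.

# Brute-force isotopologue pattern by full enumeration over every atom's
# isotope state; only feasible for tiny compositions (<= ~6 atoms).
brute_force_pattern <- function(counts, q15 = 0.00364) {
  iso <- list(
    C = data.frame(off = c(0, 1), dm = c(0, 1.0033548),
                   ab = c(1 - 0.0107, 0.0107)),
    H = data.frame(off = c(0, 1), dm = c(0, 1.0062767),
                   ab = c(1 - 0.000115, 0.000115)),
    N = data.frame(off = c(0, 1), dm = c(0, 0.9970349),
                   ab = c(1 - q15, q15)),
    O = data.frame(off = c(0, 1, 2), dm = c(0, 1.0042169, 2.0042449),
                   ab = c(1 - 0.00038 - 0.00205, 0.00038, 0.00205)),
    S = data.frame(off = c(0, 1, 2, 4),
                   dm = c(0, 0.9993878, 1.9957959, 3.9950118),
                   ab = c(1 - 0.0075 - 0.0429 - 0.0001, 0.0075, 0.0429,
                          0.0001))
  )
  atoms <- rep(names(counts), counts)
  states <- lapply(atoms, function(el) seq_len(nrow(iso[[el]])))
  grid <- expand.grid(states)
  p <- rep(1, nrow(grid)); off <- rep(0, nrow(grid)); dm <- rep(0, nrow(grid))
  for (j in seq_along(atoms)) {
    tab <- iso[[atoms[j]]]
    p <- p * tab$ab[grid[[j]]]
    off <- off + tab$off[grid[[j]]]
    dm <- dm + tab$dm[grid[[j]]]
  }
  bins <- sort(unique(off))
  data.frame(
    offset = bins,
    abundance = vapply(bins, function(b) sum(p[off == b]), numeric(1)),
    mean_dmass = vapply(bins, function(b) {
      sum(p[off == b] * dm[off == b]) / sum(p[off == b])
    }, numeric(1)))
}

# Brute-force Euclidean distance from every pixel to the nearest TRUE pixel.
edt_oracle <- function(mask) {
  hits <- which(mask, arr.ind = TRUE)
  out <- matrix(NA_real_, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      out[i, j] <- sqrt(min((hits[, 1] - i)^2 + (hits[, 2] - j)^2))
    }
  }
  out
}

# Disc mask on a pixel grid (centers at integer coordinates).
disc_mask <- function(height, width, cx, cy, r_px) {
  xs <- matrix(rep(seq_len(width), each = height), height, width)
  ys <- matrix(rep(seq_len(height), width), height, width)
  (xs - cx)^2 + (ys - cy)^2 <= r_px^2
}

# Split-Gaussian trace for fit tests.
asym_gauss_trace <- function(mz, A, c0, sl, sr) {
  A * ifelse(mz < c0, exp(-(mz - c0)^2 / (2 * sl^2)),
             exp(-(mz - c0)^2 / (2 * sr^2)))
}

abeta_comp <- function() composition_from_sequence(ABETA42_SEQUENCE)
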