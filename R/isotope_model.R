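# Elemental isotope data and exact isotopologue pattern computation for
# peptides under partial 15N enrichment.

# Monoisotopic (lightest-isotope) atomic masses, IUPAC/CODATA.
.MONO_MASS <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  S = 31.97207100
)

.PROTON_MASS <- 1.007276

# Mass excess of each heavier isotope over the lightest, and its natural
# abundance, keyed by nominal neutron-count offset.
.ISOTOPES <- list(
  C = list(offset = c(0L, 1L), dmass = c(0, 1.0033548),
           abundance = c(1 - 0.0107, 0.0107)),
  H = list(offset = c(0L, 1L), dmass = c(0, 1.0062767),
           abundance = c(1 - 0.000115, 0.000115)),
  N = list(offset = c(0L, 1L), dmass = c(0, 0.9970349),
           abundance = c(1 - 0.00364, 0.00364)),
  O = list(offset = c(0L, 1L, 2L), dmass = c(0, 1.0042169, 2.0042449),
           abundance = c(1 - 0.00038 - 0.00205, 0.00038, 0.00205)),
  S = list(offset = c(0L, 1L, 2L, 4L), dmass = c(0, 0.9993878, 1.9957959, 3.9950118),
           abundance = c(1 - 0.0075 - 0.0429 - 0.0001, 0.0075, 0.0429, 0.0001))
)

# 15N - 14N mass difference; one labeled nitrogen shifts the molecule by this.
.DELTA_15N <- 0.9970349

# Natural 15N abundance; enrichment at this value is the unlabeled identity case.
.Q_NATURAL_15N <- 0.00364

# Monoisotopic residue formulas (amino acid minus water), canonical 20 codes.
.RESIDUE_FORMULA <- list(
  G = c(C = 2, H = 3, N = 1, O = 1, S = 0),
  A = c(C = 3, H = 5, N = 1, O = 1, S = 0),
  S = c(C = 3, H = 5, N = 1, O = 2, S = 0),
  P = c(C = 5, H = 7, N = 1, O = 1, S = 0),
  V = c(C = 5, H = 9, N = 1, O = 1, S = 0),
  T = c(C = 4, H = 7, N = 1, O = 2, S = 0),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1, S = 0),
  I = c(C = 6, H = 11, N = 1, O = 1, S = 0),
  N = c(C = 4, H = 6, N = 2, O = 2, S = 0),
  D = c(C = 4, H = 5, N = 1, O = 3, S = 0),
  Q = c(C = 5, H = 8, N = 2, O = 2, S = 0),
  K = c(C = 6, H = 12, N = 2, O = 1, S = 0),
  E = c(C = 5, H = 7, N = 1, O = 3, S = 0),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1, S = 0),
  F = c(C = 9, H = 9, N = 1, O = 1, S = 0),
  R = c(C = 6, H = 12, N = 4, O = 1, S = 0),
  Y = c(C = 9, H = 9, N = 1, O = 2, S = 0),
  W = c(C = 11, H = 10, N = 2, O = 1, S = 0)
)

#' Amyloid-beta 1-42 sequence
#'
#' One-letter sequence of human A-beta 1-42, the peptide whose isotopologue
#' envelope carries the nitrogen index.
#' @export
ABETA42_SEQUENCE <- "DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVVIA"

#' Elemental composition of a peptide
#'
#' Sums monoisotopic residue formulas over a one-letter amino-acid sequence
#' and, for free termini, adds one water (H2O).
#'
#' @param sequence Character scalar of canonical one-letter amino-acid codes.
#' @param termini `"free"` (default; condensed chain plus one water) or a
#'   named numeric vector of extra atom counts to add instead (e.g. for
#'   modified termini), with names among C, H, N, O, S.
#' @return Named integer vector of atom counts (C, H, N, O, S), class
#'   `peptide_composition`.
#' @examples
#' composition_from_sequence("G")   # glycine: C2 H5 N1 O2
#' composition_from_sequence(ABETA42_SEQUENCE)[["N"]]  # 55 nitrogens
#' @export
composition_from_sequence <- function(sequence, termini = "free") {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  letters1 <- strsplit(sequence, "")[[1]]
  bad <- which(!letters1 %in% names(.RESIDUE_FORMULA))
  if (length(bad) > 0L) {
    stop(sprintf("unknown residue '%s' at position %d", letters1[bad[1]], bad[1]))
  }
  comp <- Reduce(`+`, .RESIDUE_FORMULA[letters1])
  if (identical(termini, "free")) {
    extra <- c(C = 0, H = 2, N = 0, O = 1, S = 0)
  } else {
    stopifnot(is.numeric(termini), !is.null(names(termini)))
    extra <- c(C = 0, H = 0, N = 0, O = 0, S = 0)
    extra[names(termini)] <- termini
  }
  comp <- comp + extra
  if (any(comp < 0)) stop("negative atom count after terminal adjustment")
  storage.mode(comp) <- "integer"
  class(comp) <- "peptide_composition"
  comp
}

#' Monoisotopic m/z of a composition
#'
#' @param comp Named atom-count vector (C, H, N, O, S).
#' @param charge Positive integer charge (protons added).
#' @return (sum of lightest-isotope masses + charge * proton) / charge, in Da.
#' @examples
#' ab <- composition_from_sequence(ABETA42_SEQUENCE)
#' monoisotopic_mz(ab, 1)  # 4512.28
#' @export
monoisotopic_mz <- function(comp, charge = 1L) {
  if (!is.numeric(charge) || length(charge) != 1L || charge < 1) {
    stop("charge must be a positive integer")
  }
  m <- sum(unclass(comp)[names(.MONO_MASS)] * .MONO_MASS)
  (m + charge * .PROTON_MASS) / charge
}

#' Enrichment parameters for 15N labeling
#'
#' @param q Probability that a nitrogen atom is 15N; the unlabeled case is
#'   the natural abundance 0.00364.
#' @return List with the 15N fraction, class `enrichment_params`.
#' @export
enrichment_params <- function(q = .Q_NATURAL_15N) {
  stopifnot(is.numeric(q), length(q) == 1L, q >= 0, q <= 1)
  structure(list(q = q), class = "enrichment_params")
}

# Convolve two (prob, prob-weighted-mass) distributions over nominal-offset
# bins. Each argument is a list(p = numeric, s = numeric) indexed from
# offset 0; s[k] = sum over fine states in bin k of prob * mass-excess.
.conv_pm <- function(a, b, prune = 0) {
  na <- length(a$p); nb <- length(b$p)
  p <- rep(0, na + nb - 1L)
  s <- rep(0, na + nb - 1L)
  for (i in seq_len(na)) {
    if (a$p[i] == 0 && a$s[i] == 0) next
    idx <- i:(i + nb - 1L)
    p[idx] <- p[idx] + a$p[i] * b$p
    s[idx] <- s[idx] + a$p[i] * b$s + a$s[i] * b$p
  }
  if (prune > 0) {
    keep <- max(which(p > prune))
    p <- p[seq_len(keep)]; s <- s[seq_len(keep)]
  }
  list(p = p, s = s)
}

# n-fold self-convolution by binary exponentiation.
.conv_power <- function(base, n, prune = 0) {
  result <- list(p = 1, s = 0)
  while (n > 0L) {
    if (n %% 2L == 1L) result <- .conv_pm(result, base, prune)
    base <- if (n > 1L) .conv_pm(base, base, prune) else base
    n <- n %/% 2L
  }
  result
}

# Single-element aggregated distribution as (p, s) from offset 0.
.element_pm <- function(iso) {
  n <- max(iso$offset) + 1L
  p <- rep(0, n); s <- rep(0, n)
  p[iso$offset + 1L] <- iso$abundance
  s[iso$offset + 1L] <- iso$abundance * iso$dmass
  list(p = p, s = s)
}

#' Theoretical isotopologue pattern under partial 15N enrichment
#'
#' Builds the exact isotopologue distribution of a composition by iterated
#' convolution of per-element isotope distributions, with the nitrogen
#' channel following a binomial in the 15N fraction `q`. Fine structure is
#' aggregated into nominal-mass bins (13C and 15N substitutions merged —
#' unresolvable at m/dm = 15000); each bin's mass is the abundance-weighted
#' mean of its fine states. Bins are pruned below `prune` and the pattern is
#' renormalized.
#'
#' @param comp Atom-count vector from [composition_from_sequence()].
#' @param params [enrichment_params()] carrying the 15N fraction.
#' @param prune Abundance threshold below which trailing bins are dropped
#'   (before renormalization); default 1e-10.
#' @param charge Charge state for the reported m/z axis (default 1).
#' @return List of class `isotopologue_pattern` with `masses` (Da,
#'   strictly increasing, ~1 Da apart), `abundances` (sum to 1), and
#'   `enrichment_q`.
#' @export
isotopologue_pattern <- function(comp, params = enrichment_params(),
                                 prune = 1e-10, charge = 1L) {
  stopifnot(inherits(params, "enrichment_params"), prune >= 0, prune <= 1e-4)
  comp <- unclass(comp)
  q <- params$q
  acc <- list(p = 1, s = 0)
  for (el in names(.ISOTOPES)) {
    n <- comp[[el]]
    if (is.na(n) || n == 0L) next
    iso <- .ISOTOPES[[el]]
    if (el == "N") {
      iso <- list(offset = c(0L, 1L), dmass = c(0, .DELTA_15N),
                  abundance = c(1 - q, q))
    }
    acc <- .conv_pm(acc, .conv_power(.element_pm(iso), n, prune = prune / 10),
                    prune = prune / 10)
  }
  keep <- acc$p > prune
  # keep a contiguous block from the first to last surviving bin
  first <- which(keep)[1]; last <- max(which(keep))
  idx <- first:last
  p <- acc$p[idx]; s <- acc$s[idx]
  mono <- monoisotopic_mz(comp, charge)
  mean_excess <- ifelse(p > 0, s / p, (idx - 1))
  masses <- mono + mean_excess / charge
  abund <- p / sum(p)
  structure(list(masses = masses, abundances = abund,
                 offsets = idx - 1L, enrichment_q = q),
            class = "isotopologue_pattern")
}

#' Abundance-weighted centroid of a pattern
#'
#' @param pattern An `isotopologue_pattern` (or any list with `masses` and
#'   `abundances`).
#' @return Centroid mass in Da.
#' @export
pattern_centroid <- function(pattern) {
  if (length(pattern$masses) == 0L) stop("empty pattern")
  sum(pattern$masses * pattern$abundances) / sum(pattern$abundances)
}

#' Theoretical isotopologue peak ratio
#'
#' Abundance ratio of the i-th to the j-th isotopologue bin, counted 1-based
#' from the monoisotopic bin. The 4/3 ratio is the reflector-mode nitrogen
#' index oracle.
#'
#' @param pattern An `isotopologue_pattern`.
#' @param i,j 1-based bin indices from the monoisotopic bin.
#' @return abundance(i) / abundance(j).
#' @export
theoretical_peak_ratio <- function(pattern, i = 4L, j = 3L) {
  pos_i <- match(i - 1L, pattern$offsets)
  pos_j <- match(j - 1L, pattern$offsets)
  if (is.na(pos_i) || is.na(pos_j) ||
      pattern$abundances[pos_i] <= 0 || pattern$abundances[pos_j] <= 0) {
    stop("requested isotopologue bin missing or empty")
  }
  pattern$abundances[pos_i] / pattern$abundances[pos_j]
}

#' Closed-form centroid shift for 15N enrichment
#'
#' Expected centroid displacement of a pattern at enrichment `q` relative to
#' natural abundance: n_N * (q - 0.00364) * 0.99703 Da.
#'
#' @param comp Composition (uses its nitrogen count).
#' @param q 15N fraction.
#' @return Shift in Da.
#' @export
centroid_shift_15n <- function(comp, q) {
  unclass(comp)[["N"]] * (q - .Q_NATURAL_15N) * .DELTA_15N
}

#' Export a pattern as a two-column data frame
#'
#' @param pattern An `isotopologue_pattern`.
#' @return data.frame with columns `mass` and `abundance`, writable as CSV.
#' @export
pattern_as_table <- function(pattern) {
  data.frame(mass = pattern$masses, abundance = pattern$abundances)
}
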