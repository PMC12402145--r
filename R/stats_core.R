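# Shared statistical primitives: Pearson with exact t-based p,
# Benjamini-Hochberg, one-sided Fisher's exact, paired t, and the
# noncentral-t minimum-sample-size power utility.

#' Pearson correlation with two-sided p
#'
#' Product-moment r with the exact t reference distribution:
#' t = r * sqrt((n - 2) / (1 - r^2)) against t(n - 2).
#'
#' @param x,y Numeric vectors of equal length (n >= 3), both non-constant.
#' @param method `"t"` (exact t transform, default) or `"permutation"`
#'   (two-sided permutation p; useful at very small n).
#' @param n_perm Number of permutations when `method = "permutation"`.
#' @param seed Seed for the permutation draw.
#' @return List: `r`, `p_two_sided`, `n`.
#' @export
pearson <- function(x, y, method = c("t", "permutation"), n_perm = 10000L,
                    seed = 1L) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input: correlation undefined")
  }
  if (method == "t") {
    ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
    return(list(r = unname(ct$estimate), p_two_sided = ct$p.value,
                n = length(x)))
  }
  r_obs <- stats::cor(x, y)
  r_perm <- .with_seed(seed, vapply(seq_len(n_perm), function(i) {
    stats::cor(x, sample(y))
  }, numeric(1)))
  p <- (1 + sum(abs(r_perm) >= abs(r_obs) - 1e-12)) / (n_perm + 1)
  list(r = r_obs, p_two_sided = p, n = length(x))
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up q_i = min over j >= rank(i) of m * p_(j) / j, capped at 1.
#'
#' @param p Vector of p-values in [0, 1].
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' One-sided (greater) Fisher's exact test
#'
#' Hypergeometric upper tail at the observed top-left cell of the 2x2 table
#' rows = (in list, not in list), columns = (in set, not in set).
#'
#' @param a,b,c,d Non-negative integer cell counts: a = in-list-in-set,
#'   b = in-list-not-set, c = not-list-in-set, d = neither.
#' @return One-sided p-value.
#' @export
fisher_exact_greater <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  stopifnot(all(cells >= 0), all(cells == round(cells)))
  if (sum(cells) == 0) stop("all-zero contingency table")
  stats::fisher.test(matrix(c(a, b, c, d), nrow = 2),
                     alternative = "greater")$p.value
}

#' Power of a t test at sample size n
#'
#' Exact power via the noncentral t distribution. One-sample tests use
#' noncentrality d * sqrt(n) with n - 1 df; the two-sample (equal-n) test
#' uses d * sqrt(n / 2) with 2n - 2 df.
#'
#' @param n Per-group sample size (>= 2).
#' @param d Standardized effect size (> 0).
#' @param alpha Significance level.
#' @param test `"one_sample_one_sided"`, `"one_sample_two_sided"` or
#'   `"two_sample"` (two-sided).
#' @return Power in [0, 1].
#' @export
t_test_power <- function(n, d, alpha = 0.05,
                         test = c("one_sample_one_sided",
                                  "one_sample_two_sided", "two_sample")) {
  test <- match.arg(test)
  stopifnot(n >= 2, d > 0, alpha > 0, alpha < 1)
  if (test == "two_sample") {
    df <- 2 * n - 2
    ncp <- d * sqrt(n / 2)
    crit <- stats::qt(1 - alpha / 2, df)
    return(stats::pt(crit, df, ncp, lower.tail = FALSE) +
             stats::pt(-crit, df, ncp))
  }
  df <- n - 1
  ncp <- d * sqrt(n)
  if (test == "one_sample_one_sided") {
    crit <- stats::qt(1 - alpha, df)
    stats::pt(crit, df, ncp, lower.tail = FALSE)
  } else {
    crit <- stats::qt(1 - alpha / 2, df)
    stats::pt(crit, df, ncp, lower.tail = FALSE) + stats::pt(-crit, df, ncp)
  }
}

#' Minimum sample size reaching a target power
#'
#' Smallest integer n (from 2 upward) whose exact noncentral-t power meets
#' the target. The default one-sample one-sided configuration reproduces the
#' a priori minima n = 3 at d = 2.5 and n = 5 at d = 1.5 (alpha 0.05,
#' power 0.8).
#'
#' @param d Standardized effect size (> 0).
#' @param alpha Significance level (default 0.05).
#' @param target_power Target power (default 0.8).
#' @param test Test family, as in [t_test_power()].
#' @param n_max Search ceiling (default 1e6); exceeding it is an error.
#' @return Integer minimum n.
#' @export
min_n_power <- function(d, alpha = 0.05, target_power = 0.8,
                        test = "one_sample_one_sided", n_max = 1e6) {
  stopifnot(d > 0, alpha > 0, alpha < 1, target_power > 0, target_power < 1)
  n <- 2L
  while (t_test_power(n, d, alpha, test) < target_power) {
    n <- n + 1L
    if (n > n_max) stop("target power unreachable within n_max")
  }
  n
}

#' Two-sided paired t test
#'
#' @param x,y Paired numeric vectors (equal length >= 2).
#' @return List: `t`, `p_two_sided`, `df`, `undefined` (TRUE when the
#'   differences have zero variance; x identical to y gives t = 0, p = 1 by
#'   convention).
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(list(t = 0, p_two_sided = 1, df = length(d) - 1,
                  undefined = TRUE))
    }
    return(list(t = NA_real_, p_two_sided = NA_real_, df = length(d) - 1,
                undefined = TRUE))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), p_two_sided = tt$p.value,
       df = unname(tt$parameter), undefined = FALSE)
}
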