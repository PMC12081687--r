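#' Welch's two-sample t test
#'
#' Two-tailed Welch (unequal-variance) t test with Satterthwaite degrees of
#' freedom, the package-wide test for comparing per-site quantities between
#' groups. Thin broom-style wrapper around [stats::t.test()].
#'
#' @param a,b Numeric vectors (each of length >= 2).
#' @return A one-row tibble with `estimate` (mean of `a` minus mean of `b`),
#'   `statistic`, `df` and `p_value`.
#' @export
welch_t_test <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) {
    stop("each sample needs at least 2 values", call. = FALSE)
  }
  if (stats::var(a) + stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(tibble::tibble(estimate = 0, statistic = 0, df = NA_real_,
        p_value = 1))
    }
    stop("both samples have zero variance", call. = FALSE)
  }
  ht <- t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  tibble::tibble(
    estimate = unname(ht$estimate[1] - ht$estimate[2]),
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value
  )
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Zeros are dropped; ties receive mid-ranks. For `n <= exact_max` nonzero
#' differences the two-sided p-value is exact, computed from the full null
#' distribution of the positive-rank sum over all 2^n sign assignments
#' (evaluated by a generating-function convolution over doubled mid-ranks,
#' which is feasible well past n = 25). Above that, the normal approximation
#' with tie-corrected variance and continuity correction is used.
#'
#' @param diffs Numeric vector of paired differences.
#' @param exact_max Largest n for which the exact distribution is used.
#' @return One-row tibble with `statistic` (W+, the positive-rank sum),
#'   `n_nonzero`, `p_value` and `method`. With fewer than 6 nonzero
#'   differences `p_value` is `NA` with a warning (the exact test carries no
#'   resolution there).
#' @export
wilcoxon_signed_rank <- function(diffs, exact_max = 25) {
  d <- as.numeric(diffs)
  d <- d[is.finite(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all differences are zero; p-value undefined")
    return(tibble::tibble(statistic = NA_real_, n_nonzero = 0L,
      p_value = NA_real_, method = "degenerate"))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n < 6) {
    warning("fewer than 6 nonzero differences; exact Wilcoxon p undefined")
    return(tibble::tibble(statistic = w, n_nonzero = as.integer(n),
      p_value = NA_real_, method = "degenerate"))
  }
  if (n <= exact_max) {
    p <- wsr_exact_p(r, w)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation"
  }
  tibble::tibble(statistic = w, n_nonzero = as.integer(n), p_value = p,
    method = method)
}

# Exact two-sided p for the positive-rank sum given the (possibly tied)
# rank vector. Doubling the mid-ranks makes all rank values integral; the
# null distribution is the coefficient vector of prod_i (1 + x^(2 r_i)) / 2^n.
wsr_exact_p <- function(ranks, w) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  cf <- numeric(total + 1)
  cf[1] <- 1
  for (ri in r2) {
    shifted <- c(numeric(ri), cf[seq_len(total + 1 - ri)])
    cf <- cf + shifted
  }
  cf <- cf / 2^length(r2)
  support <- 0:total            # doubled W values
  w2 <- round(2 * w)
  p_le <- sum(cf[support <= w2])
  p_ge <- sum(cf[support >= w2])
  min(1, 2 * min(p_le, p_ge))
}

#' 1-D Wasserstein distance between two binned histograms
#'
#' For histograms on a common uniform binning the earth mover's distance
#' reduces to the integrated absolute difference of the CDFs:
#' `sum(|CDF1 - CDF2|) * bin_width`, in the units of the support.
#'
#' @param h1,h2 Non-negative vectors of equal length, each summing to 1
#'   (unnormalized input is normalized with a warning).
#' @param bin_width Common bin width (e.g. mm).
#' @return The distance as a bare number.
#' @export
wasserstein_1d <- function(h1, h2, bin_width) {
  stopifnot(length(h1) == length(h2), all(h1 >= 0), all(h2 >= 0))
  if (abs(sum(h1) - 1) > 1e-8 || abs(sum(h2) - 1) > 1e-8) {
    warning("histograms do not sum to 1; normalizing")
  }
  h1 <- h1 / sum(h1)
  h2 <- h2 / sum(h2)
  sum(abs(cumsum(h1) - cumsum(h2))) * bin_width
}

#' 95% t confidence interval over sites
#'
#' Mean with `mean +/- t(0.975, n - 1) * sd / sqrt(n)` over per-site values;
#' the cross-institution uncertainty convention used for all regional
#' percentages.
#'
#' @param x Per-site values (length >= 2).
#' @return One-row tibble with `mean`, `low`, `high`, `n_sites`.
#' @export
ci95_over_sites <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2) stop("need at least 2 sites for a confidence interval",
    call. = FALSE)
  m <- mean(x)
  half <- qt(0.975, n - 1) * sd(x) / sqrt(n)
  tibble::tibble(mean = m, low = m - half, high = m + half,
    n_sites = as.integer(n))
}
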