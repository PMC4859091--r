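# Rank-based equivalence testing: Hodges-Lehmann point estimate and
# confidence interval from Walsh averages, and the two one-sided tests
# (TOST) restatement via the Wilcoxon signed-rank statistic.

# All n(n+1)/2 Walsh averages (d_i + d_j)/2, i <= j, sorted.
walsh_averages <- function(diffs) {
  n <- length(diffs)
  s <- outer(diffs, diffs, "+") / 2
  sort(s[lower.tri(s, diag = TRUE)])
}

#' Hodges-Lehmann estimate of a paired shift
#'
#' The median of the Walsh averages `(d_i + d_j)/2` over all pairs
#' `i <= j` -- the rank-based location estimate associated with the Wilcoxon
#' signed-rank test.
#'
#' @param diffs Numeric vector of paired differences (length >= 1).
#' @return The estimate.
#' @export
#' @examples
#' hl_estimate(c(1, 2, 3))   # 2: Walsh set {1, 1.5, 2, 2, 2.5, 3}
hl_estimate <- function(diffs) {
  if (length(diffs) == 0L) stop("need at least one difference")
  stats::median(walsh_averages(diffs))
}

#' Rank-based confidence interval for a paired shift
#'
#' Orders the Walsh averages and reads the interval bounds at the ranks
#' given by the Wilcoxon signed-rank critical values: exactly (via
#' `qsignrank`) for `n <= 50`, by the normal approximation for larger
#' samples. The smallest sample with an attainable two-sided 90% interval
#' is `n = 6`.
#'
#' @param diffs Paired differences, length >= 6.
#' @param confidence Confidence level (default 0.90).
#' @return Numeric `c(low, high)` with attribute `"confidence"`.
#' @export
hl_confidence_interval <- function(diffs, confidence = 0.90) {
  n <- length(diffs)
  alpha <- 1 - confidence
  min_n <- 6L  # smallest n with 2^-(n-1) * 2 <= 0.10
  if (n < min_n)
    stop(sprintf("need at least %d paired differences for a two-sided %d%% interval",
                 min_n, round(100 * confidence)))
  w <- walsh_averages(diffs)
  M <- n * (n + 1) / 2
  if (n <= 50L) {
    qu <- stats::qsignrank(alpha / 2, n)
    if (qu == 0) qu <- 1
  } else {
    mu <- M / 2
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
    qu <- max(1, round(mu - stats::qnorm(1 - alpha / 2) * sigma))
  }
  ql <- M - qu
  structure(c(w[qu], w[ql + 1]), confidence = confidence)
}

#' Equivalence margin from a reference mean
#'
#' The margin is a fraction (conventionally 20%) of the reference
#' condition's mean -- e.g. a reference accuracy of 0.75 yields
#' `delta = 0.15`.
#'
#' @param reference_mean Mean of the reference variable, in `(0, 1]`.
#' @param fraction Fraction of the reference mean (default 0.2).
#' @return The margin `delta`.
#' @export
compute_delta <- function(reference_mean, fraction = 0.2) {
  if (reference_mean <= 0 || reference_mean > 1)
    stop("reference_mean must lie in (0, 1]")
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  fraction * reference_mean
}

#' Interval-inclusion equivalence decision
#'
#' Equivalence holds when the confidence interval lies strictly inside
#' `(-delta, delta)`.
#'
#' @param ci_low,ci_high Interval bounds.
#' @param delta Equivalence margin, `> 0`.
#' @return Logical.
#' @export
equivalence_decision <- function(ci_low, ci_high, delta) {
  if (delta <= 0) stop("delta must be positive")
  (ci_low > -delta) && (ci_high < delta)
}

# One-sided Wilcoxon signed-rank p-value for H0: theta = mu; exact when the
# shifted sample has no ties or zeros and n <= 50, else normal approximation
# with tie correction. Kept internal so the TOST and the rank CI share one
# construction (they are then decision-equivalent on continuous data).
signed_rank_p <- function(x, mu, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  d <- x - mu
  n_all <- length(d)
  zeros <- d == 0
  d <- d[!zeros]
  n <- length(d)
  if (n == 0L) return(1)
  r <- rank(abs(d))
  Tplus <- sum(r[d > 0])
  exact <- n <= 50L && !any(zeros) && !anyDuplicated(abs(d))
  if (exact) {
    if (alternative == "greater")
      1 - stats::psignrank(Tplus - 1, n)
    else
      stats::psignrank(Tplus, n)
  } else {
    mu_T <- n * (n + 1) / 4
    ties <- table(r)
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 -
                    sum(ties^3 - ties) / 48)
    z <- (Tplus - mu_T) / sigma
    if (alternative == "greater") stats::pnorm(z, lower.tail = FALSE)
    else stats::pnorm(z)
  }
}

#' Rank-based equivalence test (CI inclusion with TOST restatement)
#'
#' Computes the Hodges-Lehmann estimate and rank-based confidence interval
#' of the paired shift, declares equivalence when the interval lies inside
#' `(-delta, delta)`, and also reports the two one-sided Wilcoxon
#' signed-rank tests against the margins (each at half the complement of
#' the confidence level); for a 90% interval the two procedures reject
#' together.
#'
#' @param diffs Paired differences.
#' @param delta Equivalence margin.
#' @param confidence Confidence level of the interval (default 0.90, which
#'   pairs with TOST at alpha = 0.05 per side).
#' @return An object of class `"equivalence_result"`: `hl_estimate`,
#'   `ci_low`, `ci_high`, `confidence`, `delta`, `equivalent`,
#'   `tost_p_lower`, `tost_p_upper`, `tost_equivalent`, `n`.
#' @export
equivalence_test <- function(diffs, delta, confidence = 0.90) {
  if (delta <= 0) stop("delta must be positive")
  ci <- hl_confidence_interval(diffs, confidence)
  alpha_side <- (1 - confidence) / 2
  p_lo <- signed_rank_p(diffs, -delta, "greater")  # H0: theta <= -delta
  p_hi <- signed_rank_p(diffs, delta, "less")      # H0: theta >= +delta
  structure(list(
    hl_estimate = hl_estimate(diffs),
    ci_low = ci[1], ci_high = ci[2], confidence = confidence,
    delta = delta,
    equivalent = equivalence_decision(ci[1], ci[2], delta),
    tost_p_lower = p_lo, tost_p_upper = p_hi,
    tost_equivalent = (p_lo < alpha_side) && (p_hi < alpha_side),
    n = length(diffs)
  ), class = "equivalence_result")
}

#' @export
print.equivalence_result <- function(x, ...) {
  cat(sprintf(
    "Rank-based equivalence test (n = %d)\n  HL estimate %.4f, %d%% CI (%.4f, %.4f)\n  margin +/- %.4f -> %s\n  TOST p = %.4f (lower), %.4f (upper)\n",
    x$n, x$hl_estimate, round(100 * x$confidence), x$ci_low, x$ci_high,
    x$delta, if (x$equivalent) "EQUIVALENT" else "not equivalent",
    x$tost_p_lower, x$tost_p_upper))
  invisible(x)
}
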