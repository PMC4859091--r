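# Stratified 2x2 analysis over groups: Woolf homogeneity of the
# stratum-specific odds ratios, and the Mantel-Haenszel pooled odds ratio
# with a Robins-Breslow-Greenland confidence interval.
#
# Table orientation: a = machine-condition correct, b = machine incorrect,
# c = human-condition correct, d = human incorrect, so OR < 1 means lower
# odds of a correct response in the machine-generated condition.

# Normalise strata input (data frame with a,b,c,d columns or list of 2x2
# matrices) to a data frame.
.as_strata <- function(strata) {
  if (is.data.frame(strata)) {
    stopifnot(all(c("a", "b", "c", "d") %in% names(strata)))
    return(strata)
  }
  do.call(rbind, lapply(strata, function(m) {
    m <- as.matrix(m)
    data.frame(a = m[1, 1], b = m[1, 2], c = m[2, 1], d = m[2, 2])
  }))
}

#' Per-group 2x2 condition-by-correctness tables
#'
#' @param trials Trial table from [run_experiment()].
#' @return Data frame with one row per group: `group_id`, `a` (machine
#'   correct), `b` (machine incorrect), `c` (human correct), `d` (human
#'   incorrect).
#' @export
stratum_tables <- function(trials) {
  rows <- lapply(split(trials, trials$group_id), function(g) {
    data.frame(
      group_id = g$group_id[1],
      a = sum(g$condition == "machine" & g$correct == 1L),
      b = sum(g$condition == "machine" & g$correct == 0L),
      c = sum(g$condition == "human" & g$correct == 1L),
      d = sum(g$condition == "human" & g$correct == 0L))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Woolf test of odds-ratio homogeneity across strata
#'
#' With the Haldane correction (0.5 added to every cell of every stratum,
#' unconditionally, for reproducibility), computes each stratum's log odds
#' ratio and inverse-variance weight, and the chi-squared statistic
#' `sum w_i (ln OR_i - weighted mean)^2` on `k - 1` degrees of freedom.
#' Strata with an all-zero margin in the uncorrected counts are excluded
#' with a warning.
#'
#' @param strata Data frame with columns `a`, `b`, `c`, `d`, or a list of
#'   2x2 matrices. At least 2 usable strata are required.
#' @return An `htest`-style list: `statistic` (X-squared), `parameter`
#'   (df), `p.value`, `method`.
#' @export
woolf_test <- function(strata) {
  s <- .as_strata(strata)
  bad <- (s$a + s$b == 0) | (s$c + s$d == 0) |
         (s$a + s$c == 0) | (s$b + s$d == 0)
  if (any(bad)) {
    warning(sprintf("excluding %d stratum/strata with an all-zero margin",
                    sum(bad)))
    s <- s[!bad, , drop = FALSE]
  }
  k <- nrow(s)
  if (k < 2L) stop("need at least two usable strata")
  a <- s$a + 0.5; b <- s$b + 0.5; c <- s$c + 0.5; d <- s$d + 0.5
  lor <- log(a * d / (b * c))
  w <- 1 / (1 / a + 1 / b + 1 / c + 1 / d)
  lbar <- sum(w * lor) / sum(w)
  x2 <- sum(w * (lor - lbar)^2)
  df <- k - 1L
  structure(list(statistic = c(`X-squared` = x2), parameter = c(df = df),
                 p.value = stats::pchisq(x2, df, lower.tail = FALSE),
                 method = "Woolf test of homogeneity of odds ratios",
                 data.name = deparse(substitute(strata))),
            class = "htest")
}

#' Mantel-Haenszel pooled odds ratio
#'
#' The pooled estimate `sum(a_i d_i / n_i) / sum(b_i c_i / n_i)` with a
#' confidence interval from the Robins-Breslow-Greenland variance of its
#' logarithm. For a single stratum the estimate equals the crude odds
#' ratio.
#'
#' @param strata Data frame with columns `a`, `b`, `c`, `d`, or a list of
#'   2x2 matrices.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `estimate`, `conf_int` (length 2), `conf_level`.
#' @export
mh_pooled_or <- function(strata, conf_level = 0.95) {
  s <- .as_strata(strata)
  n <- s$a + s$b + s$c + s$d
  if (any(n == 0)) stop("stratum with zero total")
  R <- s$a * s$d / n
  S <- s$b * s$c / n
  if (sum(S) == 0 || sum(R) == 0)
    stop("pooled odds ratio undefined: a cross-product sum is zero")
  or <- sum(R) / sum(S)
  # Robins-Breslow-Greenland variance of log(OR_MH)
  P <- (s$a + s$d) / n
  Q <- (s$b + s$c) / n
  v <- sum(P * R) / (2 * sum(R)^2) +
       sum(P * S + Q * R) / (2 * sum(R) * sum(S)) +
       sum(Q * S) / (2 * sum(S)^2)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- exp(log(or) + c(-1, 1) * z * sqrt(v))
  list(estimate = or, conf_int = ci, conf_level = conf_level)
}
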