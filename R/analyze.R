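# The full statistical treatment of a trial table: accuracies, equivalence,
# homogeneity, pooled odds ratio, signal-detection indices, index tests,
# between-condition correlations and the split-half bias check.

#' Accuracy summary of a trial table
#'
#' @param trials Trial table from [run_experiment()].
#' @param conditions Conditions that must be present (default both).
#' @return List with `overall`, `by_condition` (named means) and
#'   `by_participant` (data frame of per-participant-per-condition means,
#'   the pairing unit of the equivalence analysis).
#' @export
accuracy_summary <- function(trials, conditions = c("human", "machine")) {
  if (nrow(trials) == 0L) stop("empty trial table")
  missing_cond <- setdiff(conditions, unique(trials$condition))
  if (length(missing_cond) > 0L)
    stop("condition(s) absent from the trial table: ",
         paste(missing_cond, collapse = ", "))
  byc <- tapply(trials$correct, trials$condition, mean)
  agg <- stats::aggregate(correct ~ participant_id + condition, trials, mean)
  names(agg)[names(agg) == "correct"] <- "accuracy"
  nn <- stats::aggregate(correct ~ participant_id + condition, trials,
                         length)
  agg$n_trials <- nn$correct
  list(overall = mean(trials$correct),
       by_condition = byc[conditions],
       by_participant = agg)
}

# Per-participant machine-minus-human accuracy differences (paired).
paired_accuracy_diffs <- function(trials) {
  acc <- accuracy_summary(trials)$by_participant
  wide <- stats::reshape(acc[, c("participant_id", "condition", "accuracy")],
                         direction = "wide", idvar = "participant_id",
                         timevar = "condition")
  d <- wide$accuracy.machine - wide$accuracy.human
  names(d) <- wide$participant_id
  d[!is.na(d)]
}

#' Spearman rank correlation
#'
#' Mid-ranks for ties, two-sided p-value (exact for small untied samples,
#' asymptotic otherwise, as in [stats::cor.test()]).
#'
#' @param x,y Numeric vectors of equal length `>= 3`.
#' @return List with `rho` and `p`.
#' @export
rank_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("rank correlation undefined for a constant vector")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Split-half response-bias check for the machine block
#'
#' Computes each participant's B''d separately on the first and second half
#' of their machine-generated block (by presentation order) and compares the
#' halves with a paired two-sided Wilcoxon signed-rank test. A participant
#' whose half lacks self or other trials is excluded with a warning. When
#' every paired difference is zero the p-value is reported as 1 by
#' convention (with a warning).
#'
#' @param trials Trial table with `trial_index` present.
#' @return List with `mean_bias_first`, `mean_bias_second`, `p`, `n_used`,
#'   `excluded` (participant ids).
#' @export
split_half_bias <- function(trials) {
  mach <- trials[trials$condition == "machine", ]
  if (nrow(mach) == 0L) stop("no machine-condition trials")
  half_bias <- function(d) {
    n_self <- sum(d$relation == "self"); n_other <- sum(d$relation == "other")
    if (n_self == 0L || n_other == 0L) return(NA_real_)
    H <- correct_rate(sum(d$relation == "self" & d$response == "yes"), n_self)
    F <- correct_rate(sum(d$relation == "other" & d$response == "yes"),
                      n_other)
    b_double_prime_d(H, F)
  }
  per <- lapply(split(mach, mach$participant_id), function(d) {
    d <- d[order(d$trial_index), ]
    k <- nrow(d) %/% 2L
    c(first = half_bias(d[seq_len(k), ]),
      second = half_bias(d[(k + 1L):nrow(d), ]))
  })
  mat <- do.call(rbind, per)
  usable <- stats::complete.cases(mat)
  if (any(!usable))
    warning(sprintf("excluding %d participant(s) with an unusable half",
                    sum(!usable)))
  m <- mat[usable, , drop = FALSE]
  if (nrow(m) == 0L) stop("no participant has usable halves")
  dif <- m[, "second"] - m[, "first"]
  if (all(dif == 0)) {
    warning("all split-half differences are zero; p = 1 by convention")
    p <- 1
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(m[, "first"], m[, "second"], paired = TRUE,
                         exact = FALSE)$p.value)
  }
  list(mean_bias_first = mean(m[, "first"]),
       mean_bias_second = mean(m[, "second"]),
       p = p, n_used = nrow(m),
       excluded = rownames(mat)[!usable])
}

#' Full analysis of a style-attribution trial table
#'
#' Runs the whole statistical treatment: per-condition accuracies; the
#' equivalence margin as `delta_fraction` of the reference condition's mean;
#' the Hodges-Lehmann estimate and rank-based confidence interval of the
#' paired machine-minus-human accuracy difference, with the TOST
#' restatement; Woolf homogeneity and the Mantel-Haenszel pooled odds ratio
#' over group strata; per-participant A' and B''d with paired Wilcoxon
#' comparisons between conditions; Spearman correlations of the indices
#' across conditions; and the split-half bias check of the machine block.
#'
#' @param trials Trial table (data frame or path to a CSV written by
#'   [write_trial_csv()]).
#' @param delta_fraction Fraction of the reference mean defining the margin
#'   (default 0.2).
#' @param confidence Confidence level of the equivalence interval
#'   (default 0.90).
#' @param alpha Significance level for the index comparisons (default 0.05).
#' @param reference_condition Condition whose mean anchors the margin
#'   (default `"human"`).
#' @return An object of class `"style_attribution_report"`.
#' @export
analyze_trials <- function(trials, delta_fraction = 0.2, confidence = 0.90,
                           alpha = 0.05, reference_condition = "human") {
  if (is.character(trials)) trials <- read_trial_csv(trials)
  acc <- accuracy_summary(trials)
  delta <- compute_delta(acc$by_condition[[reference_condition]],
                         delta_fraction)
  equiv <- equivalence_test(paired_accuracy_diffs(trials), delta,
                            confidence)
  strata <- stratum_tables(trials)
  woolf <- woolf_test(strata)
  mh <- mh_pooled_or(strata)
  sdt <- sdt_summary(trials)
  wide <- function(col) {
    h <- sdt[sdt$condition == "human", ]
    m <- sdt[sdt$condition == "machine", ]
    m <- m[match(h$participant_id, m$participant_id), ]
    cbind(human = h[[col]], machine = m[[col]])
  }
  ap <- wide("a_prime"); bp <- wide("b_double_prime_d")
  p_a <- suppressWarnings(stats::wilcox.test(ap[, 1], ap[, 2], paired = TRUE,
                                             exact = FALSE)$p.value)
  p_b <- suppressWarnings(stats::wilcox.test(bp[, 1], bp[, 2], paired = TRUE,
                                             exact = FALSE)$p.value)
  structure(list(
    n_trials = nrow(trials),
    accuracy = acc,
    delta = delta,
    equivalence = equiv,
    homogeneity = woolf,
    pooled_or = mh,
    sdt = sdt,
    index_tests = list(
      a_prime = list(mean_human = mean(ap[, 1]), mean_machine = mean(ap[, 2]),
                     p = p_a, significant = p_a < alpha),
      b_double_prime_d = list(mean_human = mean(bp[, 1]),
                              mean_machine = mean(bp[, 2]),
                              p = p_b, significant = p_b < alpha)),
    correlations = list(
      a_prime = rank_correlation(ap[, 1], ap[, 2]),
      b_double_prime_d = rank_correlation(bp[, 1], bp[, 2])),
    split_half = split_half_bias(trials),
    alpha = alpha
  ), class = "style_attribution_report")
}

#' @export
print.style_attribution_report <- function(x, ...) {
  acc <- x$accuracy$by_condition
  cat("Style-attribution analysis\n")
  cat(sprintf("  %d trials; mean accuracy: human %.3f, machine %.3f\n",
              x$n_trials, acc[["human"]], acc[["machine"]]))
  cat(sprintf("  equivalence margin +/- %.3f\n", x$delta))
  print(x$equivalence)
  cat(sprintf("  Woolf X-squared = %.2f, df = %d, p = %.2f\n",
              x$homogeneity$statistic, x$homogeneity$parameter,
              x$homogeneity$p.value))
  cat(sprintf("  MH pooled OR = %.2f [%.2f-%.2f]\n", x$pooled_or$estimate,
              x$pooled_or$conf_int[1], x$pooled_or$conf_int[2]))
  it <- x$index_tests
  cat(sprintf("  A':   %.3f vs %.3f, p = %.3f\n", it$a_prime$mean_human,
              it$a_prime$mean_machine, it$a_prime$p))
  cat(sprintf("  B''d: %.3f vs %.3f, p = %.3f\n",
              it$b_double_prime_d$mean_human,
              it$b_double_prime_d$mean_machine, it$b_double_prime_d$p))
  sh <- x$split_half
  cat(sprintf("  split-half bias (machine): %.3f vs %.3f, p = %.3f (n = %d)\n",
              sh$mean_bias_first, sh$mean_bias_second, sh$p, sh$n_used))
  invisible(x)
}

#' Write an analysis report as JSON
#'
#' @param report A [analyze_trials()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  obj <- list(
    n_trials = report$n_trials,
    accuracy = as.list(report$accuracy$by_condition),
    delta = report$delta,
    equivalence = unclass(report$equivalence),
    woolf = list(statistic = unname(report$homogeneity$statistic),
                 df = unname(report$homogeneity$parameter),
                 p = report$homogeneity$p.value),
    pooled_or = report$pooled_or,
    index_tests = report$index_tests,
    correlations = report$correlations,
    split_half = report$split_half)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
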