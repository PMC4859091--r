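# Nonparametric signal-detection indices: A' (discriminability) and B''d
# (response bias), computed from hit and false-alarm rates per participant
# and condition.

#' Nonparametric discriminability A'
#'
#' For hit rate `H` and false-alarm rate `F`:
#' `A' = 0.5 + (H - F)(1 + H - F) / (4 H (1 - F))` when `H >= F`, and the
#' mirrored expression `0.5 - (F - H)(1 + F - H) / (4 F (1 - H))` otherwise.
#' 0.5 is chance, 1 perfect discrimination. Degenerate rates (0 or 1) should
#' be corrected before calling (see [correct_rate()]).
#'
#' @param H,F Rates in `[0, 1]` (vectorized).
#' @return A' in `[0, 1]`.
#' @export
a_prime <- function(H, F) {
  stopifnot(all(H >= 0 & H <= 1), all(F >= 0 & F <= 1))
  up <- 0.5 + (H - F) * (1 + H - F) / (4 * H * (1 - F))
  dn <- 0.5 - (F - H) * (1 + F - H) / (4 * F * (1 - H))
  out <- ifelse(H >= F, up, dn)
  out[H == F] <- 0.5      # covers 0/0 at the corners
  out
}

#' Nonparametric response bias B''d
#'
#' `B''d = ((1 - H)(1 - F) - H F) / ((1 - H)(1 - F) + H F)`; positive values
#' mark a conservative responder (tendency to answer "no"), negative a
#' liberal one. Degenerate rates should be corrected first so the
#' denominator stays positive.
#'
#' @inheritParams a_prime
#' @return B''d in `[-1, 1]`.
#' @export
b_double_prime_d <- function(H, F) {
  stopifnot(all(H >= 0 & H <= 1), all(F >= 0 & F <= 1))
  num <- (1 - H) * (1 - F) - H * F
  den <- (1 - H) * (1 - F) + H * F
  out <- num / den
  out[den == 0] <- 0      # H = F = 0.5 boundary handled by continuity; den=0
  out                     # only at (0,1)/(1,0), where num = 0 too
}

#' Interior-corrected rate
#'
#' Replaces an observed rate of 0 with `1/(2n)` and of 1 with `1 - 1/(2n)`,
#' `n` being the number of trials of that type, keeping both indices finite.
#'
#' @param k Successes (vectorized).
#' @param n Trials.
#' @return Corrected rate in `(0, 1)`.
#' @export
correct_rate <- function(k, n) {
  p <- k / n
  n <- rep_len(n, length(p))
  p[p == 0] <- 1 / (2 * n[p == 0])
  p[p == 1] <- 1 - 1 / (2 * n[p == 1])
  p
}

#' Signal-detection counts and indices for one participant and condition
#'
#' Counts hits (yes|self), misses (no|self), false alarms (yes|other) and
#' correct rejections (no|other), corrects the rates to the interior, and
#' evaluates [a_prime()] and [b_double_prime_d()].
#'
#' @param trials Trial table from [run_experiment()].
#' @param participant Participant id.
#' @param condition `"human"` or `"machine"`.
#' @return List with `counts` (named integer vector), `H`, `F`, `a_prime`,
#'   `b_double_prime_d`.
#' @export
sdt_from_trials <- function(trials, participant, condition) {
  d <- trials[trials$participant_id == participant &
              trials$condition == condition, ]
  n_self <- sum(d$relation == "self"); n_other <- sum(d$relation == "other")
  if (n_self == 0L || n_other == 0L)
    stop(sprintf("participant %s has no %s trials in the %s condition",
                 participant,
                 if (n_self == 0L) "self" else "other", condition))
  hits <- sum(d$relation == "self" & d$response == "yes")
  fas <- sum(d$relation == "other" & d$response == "yes")
  H <- correct_rate(hits, n_self)
  F <- correct_rate(fas, n_other)
  list(counts = c(hits = hits, misses = n_self - hits, false_alarms = fas,
                  correct_rejections = n_other - fas),
       H = H, F = F, a_prime = a_prime(H, F),
       b_double_prime_d = b_double_prime_d(H, F))
}

#' Per-participant signal-detection summary
#'
#' @param trials Trial table.
#' @return Data frame with one row per participant x condition: the four
#'   counts, corrected `H` and `F`, `a_prime`, `b_double_prime_d`.
#' @export
sdt_summary <- function(trials) {
  combos <- unique(trials[, c("participant_id", "condition")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    s <- sdt_from_trials(trials, combos$participant_id[i],
                         combos$condition[i])
    data.frame(participant_id = combos$participant_id[i],
               condition = combos$condition[i],
               hits = s$counts[["hits"]], misses = s$counts[["misses"]],
               false_alarms = s$counts[["false_alarms"]],
               correct_rejections = s$counts[["correct_rejections"]],
               H = s$H, F = s$F, a_prime = s$a_prime,
               b_double_prime_d = s$b_double_prime_d)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
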