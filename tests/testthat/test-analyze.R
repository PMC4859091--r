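test_that("accuracy summaries average the correctness column", {
  tr <- data.frame(
    participant_id = rep("p1", 8), group_id = "g1",
    condition = rep(c("human", "machine"), each = 4),
    relation = "self", response = "yes",
    correct = c(1L, 1L, 1L, 0L, 1L, 1L, 0L, 1L),
    trial_index = 1:8)
  acc <- accuracy_summary(tr)
  expect_equal(unname(acc$by_condition["human"]), 0.75)
  expect_equal(unname(acc$by_condition["machine"]), 0.75)
  expect_equal(acc$overall, 0.75)
  expect_error(accuracy_summary(tr[tr$condition == "human", ]), "machine")

  all_right <- tr; all_right$correct <- 1L
  expect_equal(as.numeric(accuracy_summary(all_right)$by_condition),
               c(1, 1))
})

test_that("Spearman correlation handles perfect, inverse and tied data", {
  expect_equal(rank_correlation(1:3, 3:1)$rho, -1)
  expect_equal(rank_correlation(1:5, 1:5)$rho, 1)
  expect_error(rank_correlation(c(1, 1, 1), 1:3), "constant")
  expect_error(rank_correlation(1:3, 1:4), "equal length")
})

test_that("the Spearman p-value matches exhaustive permutation at n = 6", {
  set.seed(91)
  x <- rnorm(6); y <- rnorm(6)
  obs <- abs(cor(x, y, method = "spearman"))
  perms <- NULL
  idx <- 1:6
  # all 720 permutations via recursion
  permute <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in permute(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  rhos <- vapply(permute(idx),
                 function(p) cor(x, y[p], method = "spearman"), numeric(1))
  p_perm <- mean(abs(rhos) >= obs - 1e-12)
  expect_equal(rank_correlation(x, y)$p, p_perm, tolerance = 1e-10)
})

test_that("identical machine halves give a unit p-value by convention", {
  # two participants answering identically in both halves of the block
  mk <- function(pid) data.frame(
    participant_id = pid, group_id = "g1", condition = "machine",
    relation = rep(c("self", "other"), 4),
    response = rep(c("yes", "no"), 4),
    correct = 1L, trial_index = 1:8)
  tr <- rbind(mk("p1"), mk("p2"))
  expect_warning(sh <- split_half_bias(tr), "convention")
  expect_equal(sh$mean_bias_first, sh$mean_bias_second)
  expect_equal(sh$p, 1)
  expect_equal(sh$n_used, 2L)
})

test_that("a participant with a single-relation half is excluded, counted", {
  mk <- function(pid, rel) data.frame(
    participant_id = pid, group_id = "g1", condition = "machine",
    relation = rel, response = rep(c("yes", "no"), each = 4),
    correct = 1L, trial_index = 1:8)
  good <- mk("p1", rep(c("self", "other"), 4))
  bad <- mk("p2", rep(c("self", "other"), each = 4))  # halves one-sided
  good$response <- c("yes", "no", "no", "no", "yes", "yes", "no", "yes")
  expect_warning(sh <- split_half_bias(rbind(good, bad)), "unusable")
  expect_equal(sh$n_used, 1L)
  expect_equal(sh$excluded, "p2")
})

test_that("a criterion shift between halves moves the bias estimates", {
  set.seed(92)
  n <- 40
  rows <- lapply(seq_len(n), function(i) {
    early <- responder_spec(1.3, 1.3, 0.1, 0.1)   # liberal first half
    late <- responder_spec(1.3, 1.3, 1.4, 1.4)    # conservative second half
    rel <- rep(c("self", "other"), 4)[sample.int(8)]
    resp <- c(simulate_response(early, "machine", rel[1:4]),
              simulate_response(late, "machine", rel[5:8]))
    data.frame(participant_id = sprintf("p%02d", i), group_id = "g1",
               condition = "machine", relation = rel, response = resp,
               correct = score_trial(resp, rel), trial_index = 1:8)
  })
  sh <- suppressWarnings(split_half_bias(do.call(rbind, rows)))
  expect_lt(sh$mean_bias_first, sh$mean_bias_second)
  expect_lt(sh$p, 0.05)
})

test_that("the full report assembles every component of the treatment", {
  trials <- run_experiment(default_cohort(), seed = 808)
  rep <- suppressWarnings(analyze_trials(trials))
  expect_s3_class(rep, "style_attribution_report")
  expect_equal(rep$n_trials, 896L)
  expect_equal(rep$delta,
               0.2 * unname(rep$accuracy$by_condition["human"]))
  expect_s3_class(rep$equivalence, "equivalence_result")
  expect_equal(unname(rep$homogeneity$parameter), 13L)
  expect_true(is.finite(rep$pooled_or$estimate))
  expect_equal(nrow(rep$sdt), 112L)
  expect_true(all(c("a_prime", "b_double_prime_d") %in%
                  names(rep$index_tests)))
  expect_gte(rep$split_half$n_used, 50L)
  # report is serializable
  f <- withr::local_tempfile(fileext = ".json")
  write_report_json(rep, f)
  parsed <- jsonlite::fromJSON(f)
  expect_equal(parsed$n_trials, 896L)
  expect_equal(parsed$delta, rep$delta)
  # printing works
  expect_output(print(rep), "equivalence margin")
})

test_that("dropping flagged trials leaves the analysis runnable (a2 path)", {
  coh <- generate_cohort(
    cohort_config(n_groups = 2, group_size = 4,
                  similarity_pairs = list(c(1, 2))),
    seed = 93, spec = style_spec(n_events_target = 60L))
  trials <- run_experiment(coh, seed = 94)
  a2 <- drop_flagged(trials, flag_explainable_errors(trials, coh))
  expect_lte(nrow(a2), nrow(trials))
  acc <- accuracy_summary(a2)
  expect_true(all(acc$by_condition >= 0 & acc$by_condition <= 1))
})
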