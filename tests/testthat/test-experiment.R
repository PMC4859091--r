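test_that("a test block holds balanced, group-internal excerpt assignments", {
  coh <- default_cohort()
  p <- coh$participants[[1]]
  grp <- Filter(function(q) q$group_id == p$group_id, coh$participants)
  blk <- assemble_test_block(p, grp, seed = 3)
  expect_equal(nrow(blk), 16L)
  expect_equal(blk$condition, rep(c("human", "machine"), each = 8))
  for (cond in c("human", "machine")) {
    sub <- blk[blk$condition == cond, ]
    expect_equal(sum(sub$relation == "self"), 4L)
    expect_equal(sum(sub$relation == "other"), 4L)
  }
  mate_ids <- setdiff(vapply(grp, `[[`, character(1), "id"), p$id)
  expect_true(all(blk$source_id[blk$relation == "other"] %in% mate_ids))
  expect_true(all(blk$source_id[blk$relation == "self"] == p$id))
})

test_that("reshuffling changes order but never the assignment multiset", {
  coh <- default_cohort()
  p <- coh$participants[[5]]
  grp <- Filter(function(q) q$group_id == p$group_id, coh$participants)
  b1 <- assemble_test_block(p, grp, seed = 1)
  b2 <- assemble_test_block(p, grp, seed = 2)
  key <- function(b) sort(paste(b$condition, b$relation, b$source_id))
  expect_equal(key(b1), key(b2))
  expect_false(identical(paste(b1$condition, b1$relation, b1$source_id),
                         paste(b2$condition, b2$relation, b2$source_id)))
  # determinism
  expect_identical(assemble_test_block(p, grp, seed = 1), b1)
})

test_that("materialised excerpts are truncated melodies and valid pieces", {
  coh <- small_cohort()
  p <- coh$participants[[1]]
  grp <- coh$participants
  blk <- assemble_test_block(p, grp, seed = 9, trials_per_condition = 4,
                             build_excerpts = TRUE)
  for (r in seq_len(nrow(blk))) {
    ex <- blk$excerpt[[r]]
    if (blk$condition[r] == "human") {
      expect_lt(max(ex$events$onset), 10)
    } else {
      src <- if (blk$source_id[r] == p$id) p else grp[[blk$source_id[r]]]
      expect_true(isTRUE(validate_piece(ex, src$model)))
    }
  }
})

test_that("trial scoring follows the yes-self / no-other rule", {
  expect_equal(score_trial("yes", "self"), 1L)
  expect_equal(score_trial("yes", "other"), 0L)
  expect_equal(score_trial("no", "self"), 0L)
  expect_equal(score_trial("no", "other"), 1L)
})

test_that("the default experiment yields 896 rows, 16 per participant", {
  trials <- run_experiment(default_cohort(), seed = 8)
  expect_equal(nrow(trials), 896L)
  expect_true(all(table(trials$participant_id) == 16L))
  per <- table(trials$participant_id, trials$condition, trials$relation)
  expect_true(all(per == 4L))
  expect_false(any(trials$flagged_explainable))
})

test_that("row count scales as groups x size x 2 x trials-per-condition", {
  trials <- run_experiment(small_cohort(), seed = 4)
  expect_equal(nrow(trials), 1L * 2L * 2L * 4L)
})

test_that("a chance cohort scores at the 0.5 chance level", {
  chance <- cohort_responder_defaults()
  chance[c("sensitivity_human", "sensitivity_machine", "criterion_human",
           "criterion_machine")] <- 0
  chance$sensitivity_sd <- chance$criterion_sd <- 0
  coh <- generate_cohort(cohort_config(responders = chance), seed = 55)
  trials <- run_experiment(coh, seed = 56)
  # binomial 3-sigma band around 0.5 at n = 896
  expect_equal(mean(trials$correct), 0.5, tolerance = 3 * 0.5 / sqrt(896))
})

test_that("dropping flagged trials removes exactly those rows, idempotently", {
  trials <- run_experiment(default_cohort(), seed = 8)
  flags <- sample(nrow(trials), 19)    # e.g. 11 human + 8 machine flags
  a2 <- drop_flagged(trials, flags)
  expect_equal(nrow(a2), 877L)
  expect_identical(drop_flagged(a2), a2)    # column-based flags all FALSE
  expect_identical(drop_flagged(trials, integer(0)), trials)
  expect_error(drop_flagged(trials, c(1, nrow(trials) + 1L)),
               "nonexistent")
  expect_warning(empty <- drop_flagged(trials, rep(TRUE, nrow(trials))),
                 "all trials")
  expect_equal(nrow(empty), 0L)
})

test_that("explainable-error flags target only partner confusions", {
  coh <- generate_cohort(
    cohort_config(n_groups = 1, group_size = 4,
                  similarity_pairs = list(c(1, 2))),
    seed = 66, spec = style_spec(n_events_target = 60L))
  trials <- run_experiment(coh, seed = 67)
  flags <- flag_explainable_errors(trials, coh)
  expect_length(flags, nrow(trials))
  flagged <- trials[flags, ]
  if (nrow(flagged) > 0) {
    expect_true(all(flagged$correct == 0L))
    expect_true(all(flagged$relation == "other"))
    expect_true(all(paste(flagged$participant_id, flagged$source_id) %in%
                    c("p01 p02", "p02 p01")))
  }
  none <- flag_explainable_errors(trials,
                                  generate_cohort(cohort_config(
                                    n_groups = 1, group_size = 4),
                                    seed = 66,
                                    spec = style_spec(n_events_target = 60L)))
  expect_false(any(none))
})

test_that("trial tables round-trip through CSV", {
  trials <- run_experiment(small_cohort(), seed = 4)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trial_csv(trials, f)
  back <- read_trial_csv(f)
  expect_equal(nrow(back), nrow(trials))
  expect_equal(back$correct, trials$correct)
  expect_equal(back$response, trials$response)
})
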