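test_that("simulated styles reach the corpus target with legal melodies", {
  ts <- sample_style(style_spec(), seed = 5, participant_id = "pX")
  expect_gte(ts$total_events, 100L)
  lens <- vapply(ts$melodies, n_events, integer(1))
  expect_true(all(lens >= 4 & lens <= 12))
  expect_equal(ts$participant_id, "pX")
  # the whole set survives the length filter unchanged
  filtered <- filter_training_melodies(ts$melodies, 4)
  expect_equal(length(filtered$melodies), length(ts$melodies))
  # and the trained model supports the canonical plan
  expect_s3_class(sample_piece(train_style_model(ts), 1), "piece")
})

test_that("disjoint vocabularies give models with no shared states", {
  a <- sample_style(style_spec(pitch_vocabulary = c(60, 62, 64, 65, 67)),
                    seed = 1, participant_id = "a")
  b <- sample_style(style_spec(pitch_vocabulary = c(70, 72, 74, 76, 79)),
                    seed = 2, participant_id = "b")
  expect_length(intersect(train_style_model(a)$states,
                          train_style_model(b)$states), 0L)
})

test_that("responder yes-rates match the normal-CDF model", {
  chance <- responder_spec(0, 0, 0, 0)
  yes <- simulate_response(chance, "human", "self", n = 1e4, seed = 31)
  expect_equal(mean(yes == "yes"), 0.5, tolerance = 0.016)
  yes_o <- simulate_response(chance, "machine", "other", n = 1e4, seed = 32)
  expect_equal(mean(yes_o == "yes"), 0.5, tolerance = 0.016)

  r <- responder_spec(1, 1, 0.5, 0.5)
  hit <- simulate_response(r, "human", "self", n = 1e4, seed = 33)
  expect_lt(abs(mean(hit == "yes") - pnorm(0.5)), 0.015)   # ~3 SE
  fa <- simulate_response(r, "human", "other", n = 1e4, seed = 34)
  expect_lt(abs(mean(fa == "yes") - pnorm(-0.5)), 0.015)

  # saturating sensitivity drives the hit rate to one
  r2 <- responder_spec(20, 20, 1, 1)
  expect_equal(mean(simulate_response(r2, "human", "self", n = 500,
                                      seed = 35) == "yes"), 1)
})

test_that("estimated indices recover the analytic rates' values", {
  d <- 1.2; cc <- 0.4
  r <- responder_spec(d, d, cc, cc)
  H <- pnorm(d - cc); F <- pnorm(-cc)
  hits <- sum(simulate_response(r, "human", "self", n = 1e4,
                                seed = 41) == "yes")
  fas <- sum(simulate_response(r, "human", "other", n = 1e4,
                               seed = 42) == "yes")
  Hh <- correct_rate(hits, 1e4); Fh <- correct_rate(fas, 1e4)
  expect_lt(abs(a_prime(Hh, Fh) - a_prime(H, F)), 0.01)
  expect_lt(abs(b_double_prime_d(Hh, Fh) - b_double_prime_d(H, F)), 0.01)
})

test_that("the default cohort has 14 groups of 4", {
  coh <- default_cohort()
  expect_length(coh$participants, 56L)
  groups <- vapply(coh$participants, `[[`, character(1), "group_id")
  expect_equal(length(unique(groups)), 14L)
  expect_true(all(table(groups) == 4L))
  small <- small_cohort()
  expect_length(small$participants, 2L)
})

test_that("similarity pairs share closely perturbed transition matrices", {
  coh <- generate_cohort(
    cohort_config(n_groups = 1, group_size = 4,
                  similarity_pairs = list(c(1, 2)),
                  similarity_epsilon = 0.25),
    seed = 77, spec = style_spec(n_events_target = 60L))
  P1 <- attr(coh$participants[[1]]$training_set, "transition_matrix")
  P2 <- attr(coh$participants[[2]]$training_set, "transition_matrix")
  expect_equal(dim(P1), dim(P2))
  tv <- max(rowSums(abs(P1 - P2)) / 2)
  expect_lte(tv, 0.25)
  # same vocabulary, hence overlapping state spaces
  expect_equal(attr(coh$participants[[1]]$training_set, "pitches"),
               attr(coh$participants[[2]]$training_set, "pitches"))
})

test_that("a similarity pair spanning two groups is rejected", {
  expect_error(cohort_config(n_groups = 2, group_size = 4,
                             similarity_pairs = list(c(1, 5))),
               "two groups")
})

test_that("a cohort serializes to a browsable directory", {
  coh <- small_cohort()
  dir <- withr::local_tempdir()
  cohort_to_dir(coh, dir)
  expect_true(file.exists(file.path(dir, "groups.csv")))
  p1 <- coh$participants[[1]]$id
  mids <- list.files(file.path(dir, p1), pattern = "\\.mid$")
  expect_equal(length(mids), length(coh$participants[[1]]$training_set$melodies))
  back <- style_model_from_json(file.path(dir, p1, "style_model.json"))
  expect_equal(back$states, coh$participants[[1]]$model$states)
})
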