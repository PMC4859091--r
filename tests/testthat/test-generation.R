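test_that("the canonical plan has 16 positions in 4 constrained chunks", {
  plan <- build_piece_plan()
  expect_equal(plan$length, 16L)
  expect_length(plan$chunks, 4L)
  expect_equal(plan$constraints[1], "start")
  expect_equal(plan$constraints[4], "any")       # statement: random ending
  expect_equal(plan$constraints[8], "end")
  expect_equal(plan$constraints[12], "end")
  expect_equal(plan$constraints[16], "first")    # conclusion returns home
  expect_true(all(plan$constraints[-c(1, 4, 8, 12, 16)] == "interior"))
})

test_that("enumeration matches the hand oracle on the mirror corpus", {
  mod <- train_style_model(toy_training_set())
  plan <- build_piece_plan(n_chunks = 1)
  seqs <- vapply(enumerate_pieces(mod, plan), paste, character(1),
                 collapse = " ")
  expect_setequal(seqs, c("60 62 64 65", "60 62 64 62",
                          "65 64 62 60", "65 64 62 64"))
})

test_that("feasibility sets expand forward to exactly the valid pieces", {
  mod <- train_style_model(toy_training_set())
  plan <- build_piece_plan(n_chunks = 1)
  feas <- feasibility_filter(mod, plan, "60")
  expect_setequal(feas[[1]], c("60", "65"))   # both starts can complete
  expect_setequal(feas[[2]], c("62", "64"))
  expect_setequal(feas[[3]], c("62", "64"))
  expect_setequal(feas[[4]], c("60", "62", "64", "65"))
  # forward expansion from 60 through these sets gives exactly the valid
  # pieces (checked against enumerate_pieces elsewhere); 60's only feasible
  # continuation is 62
  cnt <- stylemark:::successors(mod, "60")
  expect_equal(intersect(names(cnt), feas[[2]]), "62")
})

test_that("an unreachable constraint raises a located infeasibility error", {
  # single melody: its end state 65 has no successors, so no continuation
  # chunk can ever leave position 8
  mod <- train_style_model(training_set(list(toy_melody(c(60, 62, 64, 65)))))
  err <- tryCatch(feasibility_filter(mod, build_piece_plan(), "60"),
                  constraint_infeasible = function(e) e)
  expect_s3_class(err, "constraint_infeasible")
  expect_match(conditionMessage(err), "position")
  expect_error(sample_piece(mod, 1), class = "constraint_infeasible")
})

test_that("the looping-interior corpus is feasible over all 16 positions", {
  mod <- train_style_model(chain_training_set())
  feas <- feasibility_filter(mod, build_piece_plan(), "60")
  expect_length(feas, 16L)
  expect_true(all(lengths(feas) > 0))
  expect_equal(feas[[16]], "60")
})

test_that("sampled pieces satisfy the plan, close transitions, and repeat
           deterministically under a seed", {
  mod <- train_style_model(chain_training_set())
  for (s in 1:40) {
    pc <- sample_piece(mod, s)
    expect_true(isTRUE(validate_piece(pc, mod)))
    expect_equal(pc$states[16], pc$states[1])
    expect_true(all(pc$states[c(8, 12)] %in% mod$end_states))
    interior <- pc$states[-c(1, 4, 8, 12, 16)]
    expect_false(any(interior %in%
                     union(mod$start_states, mod$end_states)))
  }
  expect_identical(sample_piece(mod, 7)$states, sample_piece(mod, 7)$states)
  expect_equal(n_events(sample_piece(mod, 7)), 16L)
})

test_that("sampling is sound and covers the enumerated support", {
  mod <- train_style_model(chain_training_set())
  valid <- vapply(enumerate_pieces(mod), paste, character(1),
                  collapse = " ")
  expect_equal(length(valid), 24L)   # 2 starts x 3 statement ends x 2 x 2
  sampled <- vapply(1:1500, function(s)
    paste(sample_piece(mod, s)$states, collapse = " "), character(1))
  expect_true(all(sampled %in% valid))           # soundness
  expect_gt(length(unique(sampled)), 20)         # near-complete coverage
})

test_that("a deterministic chain generates the same piece whatever the seed", {
  mod <- train_style_model(training_set(list(toy_melody(c(60, 62, 64, 65)))))
  plan <- build_piece_plan(n_chunks = 1)
  outs <- vapply(1:10, function(s)
    paste(sample_piece(mod, s, plan)$states, collapse = " "), character(1))
  expect_equal(unique(outs), "60 62 64 65")
})

test_that("relaxation rescues an over-constrained sparse model, loudly", {
  # every state is a boundary state: no interior positions are satisfiable
  mod <- train_style_model(
    training_set(list(toy_melody(c(60, 62)), toy_melody(c(62, 60))),
                 min_events = 2))
  plan <- build_piece_plan(n_chunks = 1)
  expect_error(sample_piece(mod, 1, plan), class = "constraint_infeasible")
  expect_warning(pc <- sample_piece(mod, 1, plan, relax = TRUE), "relax")
  expect_length(pc$states, 4L)
})

test_that("enumeration refuses models beyond its state cap", {
  set.seed(5)
  mels <- lapply(1:4, function(i) toy_melody(sample(60:75, 10, TRUE)))
  mod <- train_style_model(training_set(mels))
  expect_error(enumerate_pieces(mod, build_piece_plan(), max_states = 8),
               "capped")
})
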