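# Test-phase assembly and scoring: each participant hears 16 excerpts --
# 8 human-produced (own recordings vs. groupmates'), then 8 machine-generated
# (pieces from their own model vs. groupmates' models) -- and answers yes/no
# to "Does this sound like your music?".

#' Assemble one participant's test block
#'
#' Per condition, half the excerpts are self-related and half other-related;
#' the other-related ones are drawn from groupmates only, spread across them
#' round-robin (melodies without replacement per groupmate where possible).
#' Order is shuffled within each condition block, and the human-produced
#' block always precedes the machine-generated block. Human excerpts are
#' truncated to `truncate_s` seconds so length cannot cue recognition.
#' Deterministic given `seed`.
#'
#' @param participant One participant bundle from a [generate_cohort()]
#'   cohort (`id`, `group_id`, `training_set`, `model`).
#' @param group_members List of the participant bundles of the whole group
#'   (including the participant).
#' @param seed Integer seed.
#' @param trials_per_condition Excerpts per condition (default 8).
#' @param truncate_s Human-excerpt cut-off in seconds (default 10).
#' @param build_excerpts Materialise the excerpt objects (truncated melodies
#'   and sampled pieces) in an `excerpt` list-column. With `FALSE` (the
#'   default) only the bookkeeping columns are produced: `source_id`,
#'   `melody_index` for human trials, `piece_seed` for machine trials.
#' @return Data frame of `2 * trials_per_condition` rows with columns
#'   `trial_index`, `condition`, `relation`, `source_id`, `melody_index`,
#'   `piece_seed` (and `excerpt` when materialised).
#' @export
assemble_test_block <- function(participant, group_members, seed,
                                trials_per_condition = 8L,
                                truncate_s = 10, build_excerpts = FALSE) {
  tpc <- as.integer(trials_per_condition)
  half <- tpc %/% 2L
  mates <- Filter(function(m) m$id != participant$id, group_members)
  if (length(mates) == 0L)
    stop("group has no other members to draw other-related excerpts from")
  n_own <- length(participant$training_set$melodies)
  if (n_own < half)
    stop(sprintf("participant %s has %d melodies but %d self excerpts are needed",
                 participant$id, n_own, half))

  with_seed(seed, {
    piece_seeds <- sample.int(2147483646L, tpc)
    # self human: own melodies, sampled without replacement
    self_mel <- sample.int(n_own, half)
    # other human / other machine: round-robin over shuffled groupmates
    pick_mates <- function() {
      idx <- rep_len(sample(seq_along(mates)), half)
      mates[idx]
    }
    other_h <- pick_mates()
    other_m <- pick_mates()
    other_mel <- integer(half)
    used <- lapply(mates, function(m) integer(0))
    names(used) <- vapply(mates, `[[`, character(1), "id")
    for (j in seq_len(half)) {
      src <- other_h[[j]]
      avail <- setdiff(seq_along(src$training_set$melodies), used[[src$id]])
      if (length(avail) == 0L)  # fall back to reuse if a mate runs short
        avail <- seq_along(src$training_set$melodies)
      other_mel[j] <- if (length(avail) == 1L) avail else sample(avail, 1L)
      used[[src$id]] <- c(used[[src$id]], other_mel[j])
    }

    block <- data.frame(
      condition = rep(c("human", "machine"), each = tpc),
      relation = rep(rep(c("self", "other"), each = half), times = 2L),
      source_id = c(rep(participant$id, half),
                    vapply(other_h, `[[`, character(1), "id"),
                    rep(participant$id, half),
                    vapply(other_m, `[[`, character(1), "id")),
      melody_index = c(self_mel, other_mel, rep(NA_integer_, tpc)),
      piece_seed = c(rep(NA_integer_, tpc), piece_seeds)
    )
    # shuffle within each condition block; human block stays first
    ord <- c(sample.int(tpc), tpc + sample.int(tpc))
    block <- block[ord, ]
    block$trial_index <- seq_len(2L * tpc)
    rownames(block) <- NULL

    if (build_excerpts) {
      by_id <- c(stats::setNames(list(participant), participant$id),
                 stats::setNames(mates, names(used)))
      block$excerpt <- lapply(seq_len(nrow(block)), function(r) {
        src <- by_id[[block$source_id[r]]]
        if (block$condition[r] == "human") {
          truncate_excerpt(src$training_set$melodies[[block$melody_index[r]]],
                           truncate_s)
        } else {
          sample_piece(src$model, block$piece_seed[r])
        }
      })
    }
    block[, c("trial_index", setdiff(names(block), "trial_index"))]
  })
}

#' Score one attribution trial
#'
#' A trial is correct when a self-related excerpt is accepted ("yes") or an
#' other-related excerpt is rejected ("no"). Vectorized.
#'
#' @param response `"yes"` or `"no"`.
#' @param relation `"self"` or `"other"`.
#' @return Integer 0/1.
#' @export
score_trial <- function(response, relation) {
  as.integer((response == "yes" & relation == "self") |
             (response == "no" & relation == "other"))
}

#' Run the full recognition experiment over a cohort
#'
#' Assembles every participant's test block, simulates their yes/no
#' responses from their responder model, and scores each trial, yielding
#' the raw trial table (the "a1" dataset). Under the default cohort this is
#' `14 groups x 4 participants x 16 trials = 896` rows.
#'
#' @param cohort A [generate_cohort()] result.
#' @param seed Master seed.
#' @param build_excerpts Materialise excerpt objects while assembling
#'   (slower; the responses depend only on the responder model).
#' @return Data frame with one row per trial: `participant_id`, `group_id`,
#'   `condition`, `relation`, `source_id`, `melody_index`, `piece_seed`,
#'   `trial_index`, `response`, `correct`, `flagged_explainable`.
#' @export
run_experiment <- function(cohort, seed = 1L, build_excerpts = FALSE) {
  parts <- cohort$participants
  groups <- split(parts, vapply(parts, `[[`, character(1), "group_id"))
  seeds <- derive_seeds(seed, 2L * length(parts))
  rows <- vector("list", length(parts))
  i <- 0L
  for (grp in groups) {
    for (p in grp) {
      i <- i + 1L
      block <- assemble_test_block(
        p, grp, seeds[i],
        trials_per_condition = cohort$config$trials_per_condition,
        build_excerpts = build_excerpts)
      block$excerpt <- NULL
      block$response <- simulate_response(p$responder, block$condition,
                                          block$relation,
                                          seed = seeds[length(parts) + i])
      block$correct <- score_trial(block$response, block$relation)
      block <- cbind(participant_id = p$id, group_id = p$group_id, block)
      rows[[i]] <- block
    }
  }
  out <- do.call(rbind, rows)
  out$flagged_explainable <- FALSE
  rownames(out) <- NULL
  out
}

#' Drop flagged "explainable" trials
#'
#' Produces the refined trial table (the "a2" dataset) by removing the
#' trials whose attribution errors are explainable by stylistic similarity
#' between group members. The flags are an input: they come either from the
#' `flagged_explainable` column, from a logical vector, or from integer row
#' indices.
#'
#' @param trials Trial table from [run_experiment()].
#' @param flags Logical vector (length `nrow(trials)`), integer row indices,
#'   or `NULL` to use the table's own `flagged_explainable` column.
#' @return The trial table without the flagged rows. Dropping is idempotent;
#'   an empty result triggers a warning.
#' @export
drop_flagged <- function(trials, flags = NULL) {
  if (is.null(flags)) flags <- trials$flagged_explainable
  if (is.logical(flags)) {
    if (length(flags) != nrow(trials))
      stop("logical flags must match the number of rows")
    drop <- which(flags)
  } else {
    drop <- as.integer(flags)
    if (length(drop) > 0 && (min(drop) < 1L || max(drop) > nrow(trials)))
      stop("flag refers to a nonexistent row")
  }
  if (length(drop) == 0L) return(trials)
  out <- trials[-drop, , drop = FALSE]
  if (nrow(out) == 0L) warning("all trials flagged; returning empty table")
  rownames(out) <- NULL
  out
}

#' Flag errors explainable by within-group stylistic similarity
#'
#' Marks the incorrect responses to other-related excerpts whose source is
#' the participant's similarity partner (the synthetic analogue of the
#' qualitative listening that identifies confusable excerpt pairs).
#'
#' @param trials Trial table from [run_experiment()].
#' @param cohort The cohort the trials came from (its config carries the
#'   similarity pairs).
#' @return Logical flag vector aligned with `trials`.
#' @export
flag_explainable_errors <- function(trials, cohort) {
  partner <- list()
  ids <- names(cohort$participants)
  for (pr in cohort$config$similarity_pairs) {
    partner[[ids[pr[1]]]] <- ids[pr[2]]
    partner[[ids[pr[2]]]] <- ids[pr[1]]
  }
  if (length(partner) == 0L) return(rep(FALSE, nrow(trials)))
  mapply(function(pid, src, rel, corr) {
    corr == 0L && rel == "other" && identical(partner[[pid]], src)
  }, trials$participant_id, trials$source_id, trials$relation,
     trials$correct, USE.NAMES = FALSE)
}

#' Write / read a trial table as CSV
#'
#' Column order is fixed: `participant_id`, `group_id`, `trial_index`,
#' `condition`, `relation`, `source_id`, `melody_index`, `piece_seed`,
#' `response`, `correct`, `flagged_explainable`.
#'
#' @param trials Trial table.
#' @param path File path.
#' @return `path` (write) or the trial table (read).
#' @export
write_trial_csv <- function(trials, path) {
  cols <- c("participant_id", "group_id", "trial_index", "condition",
            "relation", "source_id", "melody_index", "piece_seed",
            "response", "correct", "flagged_explainable")
  utils::write.csv(trials[, intersect(cols, names(trials))], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
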