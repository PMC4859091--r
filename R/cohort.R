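# Synthetic cohort: participant styles (random transition structure over a
# small pitch vocabulary) and yes/no responders (equal-variance
# signal-detection model), so the whole pipeline runs without external data.

#' Specification of a synthetic participant style
#'
#' Describes how one participant's improvisations are simulated: a pitch
#' vocabulary of 5-8 notes, a Dirichlet-concentration parameter for the
#' random row-stochastic transition matrix, a target corpus size of about
#' 100 events, and melody lengths of 4-12 events. A small designated subset
#' of the vocabulary supplies melody-initial pitches and another the
#' melody-final pitches, mirroring improvisers' habit of opening and closing
#' phrases on favoured notes; pitches outside the boundary subsets remain
#' available to the generator's intermediary (not-start-not-end) positions.
#'
#' @param pitch_vocabulary Integer MIDI pitches, or `NULL` to sample a
#'   vocabulary of `vocab_size` pitches from the keyboard's middle range.
#' @param vocab_size Vocabulary size when sampling (default: drawn from 5-8).
#' @param concentration Dirichlet concentration of transition rows
#'   (default 1; larger values give more uniform rows).
#' @param n_events_target Minimum total corpus size in events (default 100).
#' @param melody_length_range Inclusive melody length bounds
#'   (default `c(4, 12)`).
#' @param n_start_pitches,n_end_pitches Sizes of the designated boundary
#'   subsets (defaults 2 and 2; they are disjoint).
#' @param ioi Inter-onset grid in seconds (default 0.4).
#' @param ioi_jitter Uniform onset jitter, +/- seconds (default 0.05).
#' @param note_duration Nominal event duration in seconds (default 0.3).
#' @return An object of class `"style_spec"`.
#' @export
style_spec <- function(pitch_vocabulary = NULL, vocab_size = NULL,
                       concentration = 1, n_events_target = 100L,
                       melody_length_range = c(4L, 12L),
                       n_start_pitches = 2L, n_end_pitches = 2L,
                       ioi = 0.4, ioi_jitter = 0.05, note_duration = 0.3) {
  if (!is.null(pitch_vocabulary) && length(pitch_vocabulary) < 2L)
    stop("pitch vocabulary needs >= 2 pitches")
  if (concentration <= 0) stop("concentration must be positive")
  if (melody_length_range[1] < 4L)
    stop("melodies shorter than 4 events are filtered out; raise the range")
  if (n_events_target < 4L * 1L) stop("n_events_target too small")
  structure(list(pitch_vocabulary = pitch_vocabulary,
                 vocab_size = vocab_size, concentration = concentration,
                 n_events_target = as.integer(n_events_target),
                 melody_length_range = as.integer(melody_length_range),
                 n_start_pitches = as.integer(n_start_pitches),
                 n_end_pitches = as.integer(n_end_pitches),
                 ioi = ioi, ioi_jitter = ioi_jitter,
                 note_duration = note_duration),
            class = "style_spec")
}

# Random row-stochastic matrix with Dirichlet(concentration) rows.
.random_transition_matrix <- function(k, concentration) {
  g <- matrix(stats::rgamma(k * k, shape = concentration), k, k)
  g / rowSums(g)
}

#' Perturb a transition matrix toward a fresh random one
#'
#' Returns `(1 - epsilon) * P + epsilon * Q` with `Q` a fresh Dirichlet
#' draw, so every row's total-variation distance from `P` is at most
#' `epsilon`. Used to build "similar-style" participant pairs whose mutual
#' confusions the refined analysis can then discount.
#'
#' @param P Row-stochastic matrix.
#' @param epsilon Mixing weight in `[0, 1]`.
#' @param concentration Dirichlet concentration of the perturbation.
#' @return A row-stochastic matrix of the same shape.
#' @export
perturb_transition_matrix <- function(P, epsilon, concentration = 1) {
  (1 - epsilon) * P + epsilon *
    .random_transition_matrix(nrow(P), concentration)
}

# One melody: first pitch from the start subset, Markov walk, final step
# restricted to the end subset (rows are strictly positive, so the
# restriction always renormalizes).
.walk_melody <- function(pitches, P, start_idx, end_idx, len, spec,
                         participant_id) {
  k <- length(pitches)
  idx <- integer(len)
  idx[1] <- start_idx[sample.int(length(start_idx), 1L)]
  if (len > 1L) for (i in 2:len) {
    w <- P[idx[i - 1L], ]
    if (i == len) {
      w <- w[end_idx]
      idx[i] <- end_idx[sample.int(length(end_idx), 1L, prob = w / sum(w))]
    } else {
      idx[i] <- sample.int(k, 1L, prob = w)
    }
  }
  iois <- spec$ioi + stats::runif(len, -spec$ioi_jitter, spec$ioi_jitter)
  ev <- data.frame(onset = cumsum(c(0, iois[-len])),
                   duration = pmin(spec$note_duration, spec$ioi - 0.01),
                   velocity = as.integer(sample(60:100, len, replace = TRUE)))
  ev$pitches <- as.list(pitches[idx])
  melody(ev, participant_id)
}

.walk_training_set <- function(pitches, P, spec, participant_id,
                               plan = build_piece_plan(),
                               require_feasible = TRUE) {
  k <- length(pitches)
  start_idx <- seq_len(spec$n_start_pitches)
  end_idx <- spec$n_start_pitches + seq_len(spec$n_end_pitches)
  if (max(end_idx) > k) stop("vocabulary too small for the boundary subsets")
  melodies <- list()
  total <- 0L
  cap <- 3L * spec$n_events_target
  repeat {
    len <- sample(spec$melody_length_range[1]:spec$melody_length_range[2], 1L)
    melodies[[length(melodies) + 1L]] <-
      .walk_melody(pitches, P, start_idx, end_idx, len, spec, participant_id)
    total <- total + len
    if (total >= spec$n_events_target) {
      if (!require_feasible) return(training_set(melodies, participant_id))
      ts <- training_set(melodies, participant_id)
      model <- train_style_model(ts)
      if (length(.feasible_starts(model, plan)) > 0L) return(ts)
      if (total >= cap) return(NULL)   # give up on this matrix
    }
  }
}

#' Simulate one participant's improvised training set
#'
#' Draws a random row-stochastic transition matrix over the spec's pitch
#' vocabulary and walks it to emit melodies (lengths in the spec's range,
#' onsets on the spec's jittered grid) until the corpus reaches the target
#' event count. Recording then continues, exactly as a live capture session
#' would, until the trained style model can actually support the canonical
#' piece plan; if the corpus grows to three times the target without
#' success, a fresh transition matrix is drawn.
#'
#' @param spec A [style_spec()].
#' @param seed Integer seed; the walk is deterministic given `(spec, seed)`.
#' @param participant_id Identifier stamped on the melodies.
#' @param transition_matrix Optional fixed row-stochastic matrix (used for
#'   similarity pairs); `NULL` draws one from the spec.
#' @return A [training_set()] with attributes `"pitches"` and
#'   `"transition_matrix"` recording the generating process.
#' @export
sample_style <- function(spec = style_spec(), seed = 1L,
                         participant_id = "p01",
                         transition_matrix = NULL) {
  with_seed(seed, {
    pitches <- spec$pitch_vocabulary
    if (is.null(pitches)) {
      k <- spec$vocab_size %||% sample(5:8, 1L)
      pitches <- sort(sample(48:84, k))
    }
    k <- length(pitches)
    for (attempt in 1:25) {
      # a fixed matrix is kept across attempts (rows are strictly positive,
      # so a growing corpus eventually supports the plan); otherwise each
      # attempt draws afresh
      P <- transition_matrix %||%
        .random_transition_matrix(k, spec$concentration)
      ts <- .walk_training_set(pitches, P, spec, participant_id)
      if (!is.null(ts)) {
        attr(ts, "pitches") <- pitches
        attr(ts, "transition_matrix") <- P
        return(ts)
      }
    }
    stop("could not produce a generatable corpus for this style spec")
  })
}

#' Specification of a yes/no responder
#'
#' The latent decision model behind each simulated listener: equal-variance
#' Gaussian evidence with per-condition sensitivity and criterion. On a
#' self-related excerpt the evidence is centred at the condition's
#' sensitivity, on an other-related excerpt at zero; the listener answers
#' "yes" when the evidence exceeds the condition's criterion.
#'
#' @param sensitivity_human,sensitivity_machine Sensitivities (d'-scale).
#' @param criterion_human,criterion_machine Decision criteria.
#' @return An object of class `"responder_spec"`.
#' @export
responder_spec <- function(sensitivity_human, sensitivity_machine,
                           criterion_human, criterion_machine) {
  vals <- c(sensitivity_human, sensitivity_machine,
            criterion_human, criterion_machine)
  if (any(!is.finite(vals))) stop("responder parameters must be finite")
  structure(list(sensitivity_human = sensitivity_human,
                 sensitivity_machine = sensitivity_machine,
                 criterion_human = criterion_human,
                 criterion_machine = criterion_machine),
            class = "responder_spec")
}

#' Cohort-level responder parameter distributions
#'
#' The documented default constants behind the simulated cohort. Base
#' sensitivities and criteria were solved so that the population-marginal
#' hit and false-alarm rates are (0.75, 0.25) in the human-produced
#' condition (expected accuracy 0.75, no response bias) and (0.52, 0.10) in
#' the machine-generated condition (expected accuracy 0.71, conservative
#' bias, B''d about 0.5), after integrating over between-participant normal
#' heterogeneity with sd 0.5 on sensitivities and 0.35 on criteria.
#' Participants' parameters are drawn independently across conditions.
#'
#' @return Named list with `sensitivity_human`, `criterion_human`,
#'   `sensitivity_machine`, `criterion_machine` (means), `sensitivity_sd`
#'   and `criterion_sd`.
#' @export
cohort_responder_defaults <- function() {
  list(sensitivity_human = 1.5048, criterion_human = 0.7146,
       sensitivity_machine = 1.4165, criterion_machine = 1.3578,
       sensitivity_sd = 0.5, criterion_sd = 0.35)
}

#' Simulate yes/no style-attribution responses
#'
#' Draws evidence from the responder's equal-variance Gaussian model and
#' thresholds it at the condition's criterion. Vectorized over `condition`
#' and `relation` (recycled to the longer).
#'
#' @param responder A [responder_spec()].
#' @param condition `"human"` or `"machine"` (vector allowed).
#' @param relation `"self"` or `"other"` (vector allowed).
#' @param n Number of responses when `condition`/`relation` are scalars.
#' @param seed Optional seed for a private random stream.
#' @return Character vector of `"yes"`/`"no"`.
#' @export
simulate_response <- function(responder, condition, relation, n = NULL,
                              seed = NULL) {
  if (!all(condition %in% c("human", "machine")))
    stop("condition must be 'human' or 'machine'")
  if (!all(relation %in% c("self", "other")))
    stop("relation must be 'self' or 'other'")
  len <- max(length(condition), length(relation), n %||% 1L)
  condition <- rep_len(condition, len)
  relation <- rep_len(relation, len)
  sens <- ifelse(condition == "human", responder$sensitivity_human,
                 responder$sensitivity_machine)
  crit <- ifelse(condition == "human", responder$criterion_human,
                 responder$criterion_machine)
  mu <- ifelse(relation == "self", sens, 0)
  with_seed(seed, {
    evidence <- stats::rnorm(len, mean = mu, sd = 1)
    ifelse(evidence > crit, "yes", "no")
  })
}

#' Configuration of a synthetic cohort
#'
#' @param n_groups Number of groups (default 14).
#' @param group_size Participants per group (default 4, minimum 2).
#' @param trials_per_condition Test trials per condition per participant
#'   (default 8; must be even so that self and other halves balance).
#' @param similarity_pairs List of length-2 integer vectors of participant
#'   indices (1-based over the whole cohort) who share a perturbed style;
#'   both members must sit in the same group, since stylistic confusion is
#'   only possible within a group.
#' @param similarity_epsilon Total-variation bound of the pair perturbation
#'   (default 0.25).
#' @param responders Parameter list as from [cohort_responder_defaults()].
#' @return An object of class `"cohort_config"`.
#' @export
cohort_config <- function(n_groups = 14L, group_size = 4L,
                          trials_per_condition = 8L,
                          similarity_pairs = list(),
                          similarity_epsilon = 0.25,
                          responders = cohort_responder_defaults()) {
  if (group_size < 2L) stop("group_size must be >= 2")
  if (trials_per_condition %% 2L != 0L)
    stop("trials_per_condition must be even")
  for (pr in similarity_pairs) {
    if (length(pr) != 2L) stop("similarity pairs must have two members")
    g <- ceiling(pr / group_size)
    if (g[1] != g[2])
      stop("similarity pair spans two groups; confusion must be within-group")
  }
  structure(list(n_groups = as.integer(n_groups),
                 group_size = as.integer(group_size),
                 trials_per_condition = as.integer(trials_per_condition),
                 similarity_pairs = similarity_pairs,
                 similarity_epsilon = similarity_epsilon,
                 responders = responders),
            class = "cohort_config")
}

#' Generate a synthetic cohort
#'
#' Builds `n_groups * group_size` participants: each gets a simulated
#' training set ([sample_style()]), a trained [train_style_model()] fit and
#' a [responder_spec()] drawn from the cohort-level parameter distributions.
#' The second member of each similarity pair receives a transition matrix
#' perturbed from the first member's (mixing weight
#' `similarity_epsilon`), over the same vocabulary.
#'
#' @param config A [cohort_config()].
#' @param seed Master seed; everything downstream is deterministic given it.
#' @param spec A [style_spec()] shared by all participants (vocabularies are
#'   still drawn per participant unless pinned in the spec).
#' @return An object of class `"cohort"`: list with `config` and
#'   `participants`, each participant a list with `id`, `group_id`,
#'   `training_set`, `model`, `responder`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L,
                            spec = style_spec()) {
  n <- config$n_groups * config$group_size
  seeds <- derive_seeds(seed, 2L * n)
  pair_of <- integer(n)
  for (pr in config$similarity_pairs) pair_of[max(pr)] <- min(pr)
  participants <- vector("list", n)
  rp <- config$responders
  for (i in seq_len(n)) {
    id <- sprintf("p%02d", i)
    gid <- sprintf("g%02d", ceiling(i / config$group_size))
    if (pair_of[i] > 0L) {
      partner <- participants[[pair_of[i]]]
      base <- attr(partner$training_set, "transition_matrix")
      pitches <- attr(partner$training_set, "pitches")
      pspec <- spec; pspec$pitch_vocabulary <- pitches
      P <- with_seed(seeds[i],
                     perturb_transition_matrix(base,
                                               config$similarity_epsilon,
                                               spec$concentration))
      ts <- sample_style(pspec, seeds[i], id, transition_matrix = P)
    } else {
      ts <- sample_style(spec, seeds[i], id)
    }
    responder <- with_seed(seeds[n + i], responder_spec(
      sensitivity_human = stats::rnorm(1, rp$sensitivity_human,
                                       rp$sensitivity_sd),
      sensitivity_machine = stats::rnorm(1, rp$sensitivity_machine,
                                         rp$sensitivity_sd),
      criterion_human = stats::rnorm(1, rp$criterion_human,
                                     rp$criterion_sd),
      criterion_machine = stats::rnorm(1, rp$criterion_machine,
                                       rp$criterion_sd)))
    participants[[i]] <- list(id = id, group_id = gid, training_set = ts,
                              model = train_style_model(ts),
                              responder = responder)
  }
  names(participants) <- vapply(participants, `[[`, character(1), "id")
  structure(list(config = config, participants = participants),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d participants in %d groups of %d\n",
              length(x$participants), x$config$n_groups,
              x$config$group_size))
  invisible(x)
}

#' Serialize a cohort to a directory
#'
#' Writes one SMF per training melody, one JSON per style model and
#' responder, and a CSV group table, so a synthetic cohort can be inspected
#' with ordinary MIDI tooling.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
cohort_to_dir <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (p in cohort$participants) {
    pdir <- file.path(dir, p$id)
    dir.create(pdir, showWarnings = FALSE)
    for (j in seq_along(p$training_set$melodies))
      write_midi(p$training_set$melodies[[j]],
                 file.path(pdir, sprintf("melody_%02d.mid", j)))
    style_model_to_json(p$model, file.path(pdir, "style_model.json"))
    jsonlite::write_json(unclass(p$responder),
                         file.path(pdir, "responder.json"),
                         auto_unbox = TRUE, digits = NA)
    rows[[p$id]] <- data.frame(participant_id = p$id, group_id = p$group_id,
                               n_melodies = length(p$training_set$melodies),
                               total_events = p$training_set$total_events)
  }
  utils::write.csv(do.call(rbind, rows), file.path(dir, "groups.csv"),
                   row.names = FALSE)
  invisible(dir)
}
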