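#' Train a first-order style model from a training set
#'
#' A participant's style is captured as the first-order Markov transition
#' counts between chordal events (states are pitch sets, compared by exact
#' set equality), together with the set of start states (first events of the
#' training melodies), the set of end states (last events), and per-state
#' exemplars of duration, velocity and inter-onset interval drawn from the
#' training occurrences. Melody boundaries are phrase boundaries: no
#' transition is counted across two melodies.
#'
#' @param ts A [training_set()]; every melody must hold at least 2 events.
#' @return An object of class `"style_model"` with fields `states` (state
#'   keys like `"60+64"`), `state_pitches`, `counts` (per-state named count
#'   vectors over successors), `start_states`, `end_states`, `exemplars`
#'   (per-state data frames with `duration`, `velocity`, `ioi`; `ioi` is `NA`
#'   for melody-final occurrences), `n_melodies`, `total_events`,
#'   `participant_id`.
#' @export
#' @examples
#' m1 <- melody(list(note_event(60, 0, .3), note_event(62, .4, .3),
#'                   note_event(64, .8, .3), note_event(65, 1.2, .3)), "p1")
#' train_style_model(training_set(list(m1)))
train_style_model <- function(ts) {
  if (!inherits(ts, "training_set")) stop("`ts` must be a training_set")
  if (length(ts$melodies) == 0L) stop("empty training set")
  if (any(vapply(ts$melodies, n_events, integer(1)) < 2L))
    stop("every training melody needs >= 2 events")

  key_l <- dur_l <- vel_l <- ioi_l <- pit_l <- vector("list",
                                                     length(ts$melodies))
  from_l <- to_l <- vector("list", length(ts$melodies))
  starts <- character(0); ends <- character(0)
  for (j in seq_along(ts$melodies)) {
    m <- ts$melodies[[j]]
    keys <- melody_states(m)
    n <- length(keys)
    key_l[[j]] <- keys
    dur_l[[j]] <- m$events$duration
    vel_l[[j]] <- m$events$velocity
    ioi_l[[j]] <- c(diff(m$events$onset), NA_real_)
    pit_l[[j]] <- m$events$pitches
    starts <- union(starts, keys[1])
    ends <- union(ends, keys[n])
    from_l[[j]] <- keys[-n]
    to_l[[j]] <- keys[-1]
  }
  keys_all <- unlist(key_l)
  counts <- lapply(split(unlist(to_l), unlist(from_l)), function(v) {
    tab <- table(v)
    stats::setNames(as.integer(tab), names(tab))
  })
  dur_all <- unlist(dur_l); vel_all <- unlist(vel_l); ioi_all <- unlist(ioi_l)
  idx_by_key <- split(seq_along(keys_all), keys_all)
  exemplars <- lapply(idx_by_key, function(idx)
    data.frame(duration = dur_all[idx], velocity = as.integer(vel_all[idx]),
               ioi = ioi_all[idx]))
  pitches_all <- do.call(c, pit_l)
  state_pitches <- lapply(idx_by_key, function(idx) pitches_all[[idx[1]]])
  structure(list(
    states = sort(names(state_pitches)),
    state_pitches = state_pitches,
    counts = counts,
    start_states = starts,
    end_states = ends,
    exemplars = exemplars,
    n_melodies = length(ts$melodies),
    total_events = ts$total_events,
    participant_id = ts$participant_id
  ), class = "style_model")
}

#' @export
print.style_model <- function(x, ...) {
  cat(sprintf(
    "<style_model> participant %s: %d states, %d transitions, %d melodies\n",
    x$participant_id, length(x$states),
    sum(vapply(x$counts, sum, numeric(1))), x$n_melodies))
  invisible(x)
}

# Named successor-count vector of state `s` (empty vector if none).
successors <- function(model, s) {
  cnt <- model$counts[[s]]
  if (is.null(cnt)) integer(0) else cnt
}

#' Transition probability between two states
#'
#' Maximum-likelihood estimate: the count of the `s -> t` transition divided
#' by the total number of observed successors of `s`. States with no
#' successors (seen only melody-finally) have probability 0 to everything.
#'
#' @param model A [train_style_model()] fit.
#' @param s,t State keys (e.g. `"60"`, `"60+64"`) or pitch vectors.
#' @return A probability in `[0, 1]`.
#' @export
transition_prob <- function(model, s, t) {
  if (!is.character(s)) s <- state_key(s)
  if (!is.character(t)) t <- state_key(t)
  if (!s %in% model$states) stop(sprintf("unknown state '%s'", s))
  cnt <- successors(model, s)
  tot <- sum(cnt)
  if (tot == 0) return(0)
  k <- cnt[t]
  if (is.na(k)) 0 else unname(k) / tot
}

#' Serialize a style model to JSON
#'
#' States are written as sorted pitch lists, transition counts as sparse
#' `(from, to, count)` triples, plus the start/end sets and exemplars, so a
#' model can be stored alongside the MIDI corpus it came from.
#'
#' @param model A `style_model`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
style_model_to_json <- function(model, path = NULL) {
  triples <- do.call(rbind, lapply(names(model$counts), function(from) {
    data.frame(from = from, to = names(model$counts[[from]]),
               count = as.integer(model$counts[[from]]))
  }))
  obj <- list(
    participant_id = model$participant_id,
    states = lapply(model$states, function(k) model$state_pitches[[k]]),
    state_keys = model$states,
    transition_counts = triples,
    start_states = model$start_states,
    end_states = model$end_states,
    exemplars = model$exemplars,
    n_melodies = model$n_melodies,
    total_events = model$total_events
  )
  json <- jsonlite::toJSON(obj, dataframe = "columns", na = "null",
                           auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}

#' Restore a style model from its JSON serialization
#'
#' @param path File path or a JSON string from [style_model_to_json()].
#' @return A `style_model`.
#' @export
style_model_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  counts <- list()
  tc <- obj$transition_counts
  if (length(tc$from) > 0) for (i in seq_along(tc$from)) {
    counts[[tc$from[i]]][tc$to[i]] <- as.integer(tc$count[i])
  }
  exemplars <- lapply(obj$exemplars, function(e)
    data.frame(duration = as.numeric(e$duration),
               velocity = as.integer(e$velocity),
               ioi = as.numeric(e$ioi)))
  state_pitches <- stats::setNames(
    lapply(obj$states, as.integer), obj$state_keys)
  structure(list(
    states = obj$state_keys,
    state_pitches = state_pitches,
    counts = counts,
    start_states = obj$start_states,
    end_states = obj$end_states,
    exemplars = exemplars,
    n_melodies = obj$n_melodies,
    total_events = obj$total_events,
    participant_id = obj$participant_id
  ), class = "style_model")
}
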