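#' Construct a timed note event
#'
#' A note event is the atomic unit of a performance: one note or one chord,
#' i.e. a nonempty set of MIDI pitches sounding together, with an onset time,
#' a duration and a velocity.
#'
#' @param pitches Integer vector of MIDI pitch numbers (0-127), nonempty;
#'   duplicates are dropped and the set is kept sorted.
#' @param onset Onset time in seconds, `>= 0`.
#' @param duration Duration in seconds, `> 0`.
#' @param velocity MIDI velocity, integer in 1-127.
#' @return A list of class `"note_event"`.
#' @export
#' @examples
#' note_event(c(60, 64, 67), onset = 0, duration = 0.5, velocity = 80)
note_event <- function(pitches, onset, duration, velocity = 80L) {
  pitches <- sort(unique(as.integer(pitches)))
  if (length(pitches) == 0L || anyNA(pitches))
    stop("a note event needs at least one pitch")
  if (any(pitches < 0L | pitches > 127L))
    stop("MIDI pitches must lie in 0-127")
  if (onset < 0) stop("onset must be >= 0")
  if (duration <= 0) stop("duration must be > 0")
  velocity <- as.integer(velocity)
  if (velocity < 1L || velocity > 127L) stop("velocity must lie in 1-127")
  structure(list(pitches = pitches, onset = as.numeric(onset),
                 duration = as.numeric(duration), velocity = velocity),
            class = "note_event")
}

#' Construct a melody
#'
#' A melody is an ordered sequence of [note_event()]s with non-decreasing
#' onsets, attributed to one participant. Internally events are stored as a
#' data frame with a `pitches` list-column.
#'
#' @param events A list of `note_event` objects, or a data frame with columns
#'   `onset`, `duration`, `velocity` and a `pitches` list-column. May be
#'   empty (an empty melody is valid as an edge case; training-set melodies
#'   are required to be longer downstream).
#' @param participant_id Identifier of the performer.
#' @return An object of class `"melody"` with fields `events` and
#'   `participant_id`.
#' @export
melody <- function(events = list(), participant_id = NA_character_) {
  if (is.data.frame(events)) {
    ev <- events
  } else {
    ev <- data.frame(
      onset = vapply(events, `[[`, numeric(1), "onset"),
      duration = vapply(events, `[[`, numeric(1), "duration"),
      velocity = vapply(events, `[[`, integer(1), "velocity")
    )
    ev$pitches <- lapply(events, `[[`, "pitches")
  }
  if (nrow(ev) > 0) {
    if (is.unsorted(ev$onset)) stop("melody onsets must be non-decreasing")
    if (any(ev$duration <= 0)) stop("durations must be > 0")
    if (any(lengths(ev$pitches) == 0L)) stop("events must have pitches")
  }
  rownames(ev) <- NULL
  structure(list(events = ev, participant_id = participant_id),
            class = "melody")
}

#' Number of events in a melody
#' @param m A `melody`.
#' @return Integer event count.
#' @export
n_events <- function(m) nrow(m$events)

#' @export
print.melody <- function(x, ...) {
  cat(sprintf("<melody> %d event(s), participant %s\n",
              n_events(x), x$participant_id))
  invisible(x)
}

# State keys ("60+64") of a melody's events, in order.
melody_states <- function(m) {
  vapply(m$events$pitches, state_key, character(1))
}

#' Construct a training set
#'
#' The melodies a participant improvised, after length filtering: every
#' melody must hold at least `min_events` events. `total_events` is the sum
#' of melody lengths.
#'
#' @param melodies List of `melody` objects.
#' @param participant_id Participant identifier; defaults to the first
#'   melody's.
#' @param min_events Minimum events per melody enforced here (default 4).
#' @return An object of class `"training_set"` with fields `participant_id`,
#'   `melodies` and `total_events`.
#' @export
training_set <- function(melodies, participant_id = NULL, min_events = 4L) {
  if (length(melodies) == 0L)
    stop("a training set needs at least one melody",
         call. = FALSE)
  lens <- vapply(melodies, n_events, integer(1))
  if (any(lens < min_events))
    stop(sprintf("all training melodies must have >= %d events", min_events))
  participant_id <- participant_id %||% melodies[[1]]$participant_id
  structure(list(participant_id = participant_id, melodies = melodies,
                 total_events = sum(lens)),
            class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("<training_set> participant %s: %d melodies, %d events\n",
              x$participant_id, length(x$melodies), x$total_events))
  invisible(x)
}

#' Filter melodies by minimum length into a training set
#'
#' Retains exactly the melodies with at least `min_events` events (notes or
#' chords), preserving order. Too-short improvisations are judged
#' uninformative about transition structure and dropped.
#'
#' @param melodies List of `melody` objects.
#' @param min_events Survival threshold (default 4).
#' @param participant_id Optional identifier for the resulting set.
#' @return A [training_set()].
#' @export
filter_training_melodies <- function(melodies, min_events = 4L,
                                     participant_id = NULL) {
  if (min_events < 1L) stop("min_events must be >= 1")
  keep <- melodies[vapply(melodies, n_events, integer(1)) >= min_events]
  if (length(keep) == 0L)
    stop(structure(class = c("empty_training_set", "error", "condition"),
                   list(message = sprintf(
                     "no melody has >= %d events; empty training set",
                     min_events), call = sys.call())))
  training_set(keep, participant_id = participant_id,
               min_events = min_events)
}

#' Truncate an excerpt to a maximum length in seconds
#'
#' Keeps the events whose onset, measured from the first event's onset, is
#' strictly below `max_seconds`, and re-anchors the first event at time 0.
#' Truncation makes excerpt length uninformative in the recognition task.
#' A melody already within the limit is returned unchanged.
#'
#' @param m A `melody`.
#' @param max_seconds Cut-off in seconds (default 10).
#' @return A `melody`, a prefix of the input.
#' @export
truncate_excerpt <- function(m, max_seconds = 10) {
  if (max_seconds <= 0) stop("max_seconds must be > 0")
  if (n_events(m) == 0L) return(m)
  rel <- m$events$onset - m$events$onset[1]
  keep <- rel < max_seconds
  if (all(keep)) return(m)
  ev <- m$events[keep, , drop = FALSE]
  ev$onset <- rel[keep]
  melody(ev, m$participant_id)
}

#' Group raw note messages into chordal events
#'
#' Messages whose onsets fall within `window` seconds of the first message of
#' the current group are merged into a single chord event: the pitch set is
#' their union, the onset the earliest onset, the duration the latest offset
#' minus the group onset, and the velocity the loudest member's.
#'
#' @param messages Data frame with columns `pitch`, `onset`, `duration`,
#'   `velocity`, sorted by onset (as returned by [read_midi()]).
#' @param window Simultaneity window in seconds, `>= 0` (default 0.05).
#' @param participant_id Attributed performer of the resulting melody.
#' @return A [melody()] whose event count is at most `nrow(messages)`.
#' @export
group_chords <- function(messages, window = 0.05,
                         participant_id = NA_character_) {
  if (window < 0) stop("window must be >= 0")
  if (is.null(messages) || nrow(messages) == 0L)
    return(melody(participant_id = participant_id))
  if (is.unsorted(messages$onset)) stop("messages must be sorted by onset")
  grp <- integer(nrow(messages))
  g <- 1L; anchor <- messages$onset[1]
  for (i in seq_len(nrow(messages))) {
    if (messages$onset[i] - anchor > window) {
      g <- g + 1L
      anchor <- messages$onset[i]
    }
    grp[i] <- g
  }
  rows <- split(seq_len(nrow(messages)), grp)
  ev <- data.frame(
    onset = vapply(rows, function(r) min(messages$onset[r]), numeric(1)),
    duration = vapply(rows, function(r) {
      max(messages$onset[r] + messages$duration[r]) - min(messages$onset[r])
    }, numeric(1)),
    velocity = vapply(rows, function(r) as.integer(max(messages$velocity[r])),
                      integer(1))
  )
  ev$pitches <- lapply(rows, function(r) sort(unique(messages$pitch[r])))
  melody(ev, participant_id)
}

#' Segment a message stream into melodies at silence gaps
#'
#' Utility for captures where phrase boundaries were not recorded: the stream
#' is split wherever the silence between one message's offset and the next
#' message's onset exceeds `gap` seconds, then each segment is chord-grouped.
#'
#' @param messages Data frame as in [group_chords()].
#' @param gap Minimum silence, in seconds, that separates melodies
#'   (default 2).
#' @param window Chord-grouping window passed on to [group_chords()].
#' @param participant_id Performer identifier.
#' @return List of `melody` objects.
#' @export
segment_melodies <- function(messages, gap = 2, window = 0.05,
                             participant_id = NA_character_) {
  if (is.null(messages) || nrow(messages) == 0L) return(list())
  off <- cummax(messages$onset + messages$duration)
  breaks <- which(messages$onset[-1] - off[-nrow(messages)] > gap)
  seg <- rep(seq_len(length(breaks) + 1L),
             diff(c(0L, breaks, nrow(messages))))
  lapply(split(messages, seg), group_chords, window = window,
         participant_id = participant_id)
}

#' Write melodies to a plain-text CSV
#'
#' One row per event with columns `participant_id`, `melody_index`,
#' `event_index`, `pitches` (`+`-joined MIDI numbers), `onset_s`,
#' `duration_s`, `velocity`.
#'
#' @param melodies List of `melody` objects (or a single melody).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_melody_csv <- function(melodies, path) {
  if (inherits(melodies, "melody")) melodies <- list(melodies)
  rows <- lapply(seq_along(melodies), function(i) {
    m <- melodies[[i]]
    if (n_events(m) == 0L) return(NULL)
    data.frame(participant_id = m$participant_id, melody_index = i,
               event_index = seq_len(n_events(m)),
               pitches = melody_states(m),
               onset_s = m$events$onset, duration_s = m$events$duration,
               velocity = m$events$velocity)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read melodies from the CSV written by [write_melody_csv()]
#'
#' @param path Input file path.
#' @return List of `melody` objects in `melody_index` order.
#' @export
read_melody_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$melody_index), function(d) {
    d <- d[order(d$event_index), ]
    ev <- data.frame(onset = d$onset_s, duration = d$duration_s,
                     velocity = as.integer(d$velocity))
    ev$pitches <- lapply(d$pitches, key_pitches)
    melody(ev, d$participant_id[1])
  })
}
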