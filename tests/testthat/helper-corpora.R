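# Small corpora and random generators shared across the suite.

# A melody from a plain pitch sequence on a 0.4 s grid.
toy_melody <- function(pitches, pid = "p1", ioi = 0.4, dur = 0.3) {
  ev <- data.frame(onset = (seq_along(pitches) - 1) * ioi,
                   duration = dur,
                   velocity = 80L)
  ev$pitches <- as.list(as.integer(pitches))
  melody(ev, pid)
}

# Two mirror-image four-note melodies: C D E F and F E D C.
toy_training_set <- function(pid = "p1") {
  training_set(list(toy_melody(c(60, 62, 64, 65), pid),
                    toy_melody(c(65, 64, 62, 60), pid)))
}

# Three states A=60 (boundary), B=62 (interior self-looping), C=64
# (boundary); supports the full 16-position plan.
chain_training_set <- function(pid = "p1") {
  training_set(list(toy_melody(c(60, 62, 62, 64), pid),
                    toy_melody(c(64, 62, 62, 60), pid)))
}

# Random monophonic/chordal melody for round-trip and property tests.
random_melody <- function(n = NULL, pid = "pr") {
  n <- n %||% sample(4:12, 1)
  iois <- runif(n, 0.15, 0.8)
  ev <- data.frame(onset = cumsum(c(0, iois[-n])),
                   duration = runif(n, 0.05, 0.5),
                   velocity = sample(20:120, n, replace = TRUE))
  ev$pitches <- lapply(seq_len(n), function(i)
    sort(sample(36:96, sample(1:3, 1))))
  melody(ev, pid)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random raw message table (sorted by onset) for chord-grouping tests.
random_messages <- function(n = 20) {
  onset <- sort(runif(n, 0, 5))
  data.frame(pitch = sample(40:90, n, replace = TRUE), onset = onset,
             duration = runif(n, 0.05, 0.4),
             velocity = sample(30:110, n, replace = TRUE))
}

# Memoised default cohort (a couple of seconds to build; reused widely).
.default_cohort_cache <- new.env(parent = emptyenv())
default_cohort <- function() {
  if (is.null(.default_cohort_cache$coh))
    .default_cohort_cache$coh <- generate_cohort(cohort_config(), seed = 424L)
  .default_cohort_cache$coh
}

# A fast small cohort: 1 group of 2, short corpora.
small_cohort <- function(seed = 99L, n_groups = 1L, group_size = 2L,
                         trials_per_condition = 4L, ...) {
  generate_cohort(
    cohort_config(n_groups = n_groups, group_size = group_size,
                  trials_per_condition = trials_per_condition, ...),
    seed = seed,
    spec = style_spec(n_events_target = 60L))
}
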