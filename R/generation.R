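# Constrained piece generation: unary positional constraints over a
# first-order style model, solved by a backward feasibility pass followed by
# forward sampling (never a bare random walk, so sampling cannot dead-end).

#' Build a positional constraint plan
#'
#' A plan is a vector of per-position constraints, one of:
#' \describe{
#'   \item{`"start"`}{state must be in the model's start set}
#'   \item{`"end"`}{state must be in the model's end set}
#'   \item{`"interior"`}{state must be in neither boundary set}
#'   \item{`"any"`}{unconstrained}
#'   \item{`"first"`}{state must equal the piece's first state (resolved
#'     once position 1 is chosen)}
#' }
#'
#' @param constraints Character vector of the values above.
#' @param chunks Optional list of integer position vectors marking chunk
#'   boundaries (metadata only).
#' @return An object of class `"piece_plan"`.
#' @seealso [build_piece_plan()] for the canonical 4x4 plan.
#' @export
piece_plan <- function(constraints, chunks = NULL) {
  ok <- c("start", "end", "interior", "any", "first")
  if (!all(constraints %in% ok))
    stop("constraints must be one of: ", paste(ok, collapse = ", "))
  structure(list(length = length(constraints), constraints = constraints,
                 chunks = chunks), class = "piece_plan")
}

#' The canonical statement/continuation/conclusion piece plan
#'
#' The default generated piece is 16 events in 4 chunks of 4. The statement
#' chunk opens on a start state and ends on an unconstrained ("random")
#' state; each continuation chunk ends on an end state; the conclusion chunk
#' returns to the piece's very first state. All remaining (intermediary)
#' positions must avoid both boundary sets, so the interior of the piece
#' never sounds like a phrase beginning or ending.
#'
#' @param n_chunks Number of chunks (default 4; 1 gives a statement-only
#'   plan, useful for small studies of the machinery).
#' @param chunk_length Events per chunk (default 4).
#' @return A [piece_plan()] of length `n_chunks * chunk_length`.
#' @export
build_piece_plan <- function(n_chunks = 4L, chunk_length = 4L) {
  stopifnot(n_chunks >= 1L, chunk_length >= 2L)
  len <- n_chunks * chunk_length
  cons <- rep("interior", len)
  cons[1] <- "start"
  cons[chunk_length] <- "any"                       # statement: random ending
  if (n_chunks >= 3L)
    for (k in 2:(n_chunks - 1L)) cons[k * chunk_length] <- "end"
  if (n_chunks >= 2L) cons[len] <- "first"          # conclusion: return home
  piece_plan(cons, chunks = split(seq_len(len),
                                  rep(seq_len(n_chunks), each = chunk_length)))
}

# States of `model` satisfying one constraint (first_state binds "first").
.satisfying_states <- function(model, constraint, first_state = NULL) {
  switch(constraint,
    start = intersect(model$states, model$start_states),
    end = intersect(model$states, model$end_states),
    interior = setdiff(model$states,
                       union(model$start_states, model$end_states)),
    any = model$states,
    first = {
      if (is.null(first_state)) stop("'first' constraint needs first_state")
      intersect(model$states, first_state)
    })
}

#' Backward feasibility filter
#'
#' Computes, for each plan position, the set of states from which the rest of
#' the plan can still be completed: position `L` holds the states satisfying
#' the final constraint, and position `p` holds the states that satisfy
#' constraint `p` *and* have a positively-counted transition into some state
#' feasible at `p + 1`. Forward sampling restricted to these sets can never
#' reach a dead end.
#'
#' @param model A [train_style_model()] fit.
#' @param plan A [piece_plan()].
#' @param first_state State key for the piece's first event (must be a start
#'   state); binds the `"first"` constraint.
#' @return List of `plan$length` character vectors of feasible state keys.
#'   Signals a condition of class `"constraint_infeasible"` naming the first
#'   empty position if the plan cannot be satisfied from `first_state`.
#' @export
feasibility_filter <- function(model, plan, first_state) {
  L <- plan$length
  infeasible <- function(pos) {
    stop(structure(class = c("constraint_infeasible", "error", "condition"),
                   list(message = sprintf(
                     "plan infeasible from state '%s': no feasible state at position %d",
                     first_state, pos), call = sys.call(-1))))
  }
  feas <- vector("list", L)
  feas[[L]] <- .satisfying_states(model, plan$constraints[L], first_state)
  if (length(feas[[L]]) == 0L) infeasible(L)
  for (p in rev(seq_len(L - 1L))) {
    cand <- .satisfying_states(model, plan$constraints[p], first_state)
    keep <- vapply(cand, function(s) {
      nxt <- successors(model, s)
      any(names(nxt)[nxt > 0] %in% feas[[p + 1L]])
    }, logical(1))
    feas[[p]] <- cand[keep]
    if (length(feas[[p]]) == 0L) infeasible(p)
  }
  if (!first_state %in% feas[[1L]]) infeasible(1L)
  feas
}

# Start states from which the plan is feasible, with their feasibility sets.
.feasible_starts <- function(model, plan) {
  out <- list()
  for (s in .satisfying_states(model, plan$constraints[1])) {
    feas <- tryCatch(feasibility_filter(model, plan, s),
                     constraint_infeasible = function(e) NULL)
    if (!is.null(feas)) out[[s]] <- feas
  }
  out
}

#' Sample a piece from a style model under a constraint plan
#'
#' Picks the first state uniformly among the start states from which the
#' plan is feasible, then walks forward: at each position the next state is
#' drawn with probability proportional to the model's transition counts,
#' renormalized over the next position's feasible set (the local Markov
#' statistics are preserved; only provably dead branches are removed).
#' Durations, velocities and inter-onset intervals are copied from a
#' uniformly chosen training exemplar of each state. Deterministic given
#' `(model, seed)`.
#'
#' @param model A [train_style_model()] fit.
#' @param seed Integer seed driving this piece's private random stream.
#' @param plan A [piece_plan()]; defaults to the canonical 4x4 plan.
#' @param relax If no start state is feasible, retry with `"interior"`
#'   constraints relaxed to `"any"` (last resort, announced with a warning)
#'   instead of failing.
#' @return An object of class `c("piece", "melody")` with the usual melody
#'   fields plus `states`, `seed`, `source_participant` and the `plan`.
#' @export
sample_piece <- function(model, seed, plan = build_piece_plan(),
                         relax = FALSE) {
  starts <- .feasible_starts(model, plan)
  if (length(starts) == 0L) {
    if (!relax)
      stop(structure(class = c("constraint_infeasible", "error", "condition"),
                     list(message = "no feasible first state for the plan",
                          call = sys.call())))
    warning("relaxing 'interior' constraints to 'any': model too sparse ",
            "for the strict plan", call. = FALSE)
    plan <- piece_plan(ifelse(plan$constraints == "interior", "any",
                              plan$constraints), plan$chunks)
    starts <- .feasible_starts(model, plan)
    if (length(starts) == 0L)
      stop(structure(class = c("constraint_infeasible", "error", "condition"),
                     list(message = "plan infeasible even after relaxation",
                          call = sys.call())))
  }
  with_seed(seed, {
    first <- names(starts)[[sample.int(length(starts), 1L)]]
    feas <- starts[[first]]
    keys <- character(plan$length)
    keys[1] <- first
    for (p in seq_len(plan$length)[-1]) {
      cnt <- successors(model, keys[p - 1L])
      cnt <- cnt[names(cnt) %in% feas[[p]] & cnt > 0]
      stopifnot(length(cnt) > 0L)  # guaranteed by the backward filter
      keys[p] <- names(cnt)[[
        sample.int(length(cnt), 1L, prob = cnt / sum(cnt))]]
    }
    .realize_piece(model, keys, plan, seed)
  })
}

# Turn a state-key sequence into timed events using training exemplars.
.realize_piece <- function(model, keys, plan, seed) {
  all_ioi <- unlist(lapply(model$exemplars, function(e) e$ioi))
  fallback_ioi <- stats::median(all_ioi, na.rm = TRUE)
  if (is.na(fallback_ioi)) fallback_ioi <- 0.4
  n <- length(keys)
  dur <- vel <- ioi <- numeric(n)
  for (i in seq_len(n)) {
    ex <- model$exemplars[[keys[i]]]
    row <- ex[sample.int(nrow(ex), 1L), ]
    dur[i] <- row$duration; vel[i] <- row$velocity
    ioi[i] <- if (is.na(row$ioi)) fallback_ioi else row$ioi
  }
  ev <- data.frame(onset = cumsum(c(0, ioi[-n])), duration = dur,
                   velocity = as.integer(vel))
  ev$pitches <- lapply(keys, function(k) model$state_pitches[[k]])
  out <- melody(ev, model$participant_id)
  out$states <- keys
  out$seed <- seed
  out$source_participant <- model$participant_id
  out$plan <- plan
  class(out) <- c("piece", "melody")
  out
}

#' Check that a piece satisfies its plan against a model
#'
#' Verifies every positional constraint, the first-equals-last linkage, and
#' transition closure (every adjacent state pair has a positive count).
#'
#' @param piece A [sample_piece()] result (or any object with `$states`).
#' @param model The source model.
#' @param plan The plan to check against (default: the piece's own).
#' @return `TRUE`, or a character vector describing the violations.
#' @export
validate_piece <- function(piece, model, plan = piece$plan) {
  keys <- piece$states
  bad <- character(0)
  for (p in seq_along(keys)) {
    ok_states <- .satisfying_states(model, plan$constraints[p], keys[1])
    if (!keys[p] %in% ok_states)
      bad <- c(bad, sprintf("position %d violates '%s'", p,
                            plan$constraints[p]))
  }
  for (p in seq_len(length(keys) - 1L)) {
    cnt <- successors(model, keys[p])
    if (is.na(cnt[keys[p + 1L]]) || cnt[keys[p + 1L]] <= 0)
      bad <- c(bad, sprintf("no observed transition %s -> %s at position %d",
                            keys[p], keys[p + 1L], p))
  }
  if (length(bad) == 0L) TRUE else bad
}

#' Exhaustively enumerate all valid pieces (test oracle)
#'
#' Depth-first enumeration of every state sequence that satisfies the plan
#' and has positive transition counts throughout. Intended as an independent
#' oracle for small corpora; refuses models beyond `max_states` states.
#'
#' @param model A `style_model` with at most `max_states` states.
#' @param plan A [piece_plan()].
#' @param max_states Refusal cap (default 8).
#' @return List of character vectors of state keys (possibly empty).
#' @export
enumerate_pieces <- function(model, plan = build_piece_plan(),
                             max_states = 8L) {
  if (length(model$states) > max_states)
    stop(sprintf("model has %d states; enumeration capped at %d",
                 length(model$states), max_states))
  out <- list()
  extend <- function(keys, first) {
    p <- length(keys) + 1L
    if (p > plan$length) {
      out[[length(out) + 1L]] <<- keys
      return(invisible())
    }
    cand <- .satisfying_states(model, plan$constraints[p], first)
    if (p > 1L) {
      cnt <- successors(model, keys[p - 1L])
      cand <- intersect(cand, names(cnt)[cnt > 0])
    }
    for (s in cand) extend(c(keys, s), if (p == 1L) s else first)
  }
  extend(character(0), NULL)
  out
}
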