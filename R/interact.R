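# Agent-level interaction rules, in plain R. These mirror, one rule at a
# time, what the compiled run loop does in bulk; they are the reference
# implementation used in unit tests and for stepping tiny populations.

agent_ref <- function(group, index) list(group = group, index = as.integer(index))

get_mask <- function(state, ref) {
  switch(ref$group,
         EU = 1L,
         M = state$rep_m[ref$index],
         B = state$rep_b[ref$index],
         stop("unknown group"))
}

set_mask <- function(state, ref, mask) {
  switch(ref$group,
         EU = if (mask != 1L) stop("European repertoires are immutable"),
         M = state$rep_m[ref$index] <- as.integer(mask),
         B = state$rep_b[ref$index] <- as.integer(mask))
  state
}

# Map a flat agent id in 1..N (Europeans first, then M, then B) to a ref.
flat_ref <- function(state, id) {
  if (id <= state$n_eu) return(agent_ref("EU", id))
  id <- id - state$n_eu
  if (id <= state$n_m) return(agent_ref("M", id))
  agent_ref("B", id - state$n_m)
}

#' Draw a speaker/hearer pair under the segregated contact topology
#'
#' Two distinct agents are drawn uniformly at random. A draw of two
#' Europeans is discarded and redrawn without advancing time (Europeans can
#' only speak, so such a pair could never interact). If exactly one agent is
#' European, that agent is the Speaker; between two non-Europeans roles are
#' assigned by fair coin. A European-speaker/Bozal-hearer pair is retained
#' only with probability \code{epsilon}; otherwise the draw is a null step
#' (by default a counted one, see \code{\link{model_params}}).
#'
#' @param state An \code{ng_state}.
#' @param params An \code{ng_params} (supplies \code{epsilon}).
#' @return A list with elements \code{speaker}, \code{hearer} (each a
#'   \code{list(group, index)}) and \code{null_step = FALSE}; or
#'   \code{list(null_step = TRUE)} for an epsilon-rejected draw.
#' @export
draw_pair <- function(state, params) {
  stopifnot(inherits(state, "ng_state"))
  stopifnot_params(params)
  N <- state$n_eu + state$n_m + state$n_b
  if (state$n_m + state$n_b == 0L) stop("no possible hearers")
  repeat {
    i <- sample.int(N, 1L)
    j <- sample.int(N - 1L, 1L)
    if (j >= i) j <- j + 1L
    if (i <= state$n_eu && j <= state$n_eu) next   # two Europeans: redraw
    if (i <= state$n_eu) { sp <- i; hr <- j }
    else if (j <= state$n_eu) { sp <- j; hr <- i }
    else if (stats::runif(1) < 0.5) { sp <- i; hr <- j }
    else { sp <- j; hr <- i }
    if (sp <= state$n_eu && hr > state$n_eu + state$n_m) {
      if (stats::runif(1) >= params$epsilon) {
        if (params$eps_null_advances_time)
          return(list(null_step = TRUE))
        next
      }
    }
    return(list(speaker = flat_ref(state, sp), hearer = flat_ref(state, hr),
                null_step = FALSE))
  }
}

#' Utter a language from a repertoire
#'
#' The speaker selects one language uniformly at random from her repertoire.
#'
#' @param speaker_rep Character repertoire, a non-empty subset of
#'   \code{c("E", "A", "C")}.
#' @return A single language label.
#' @export
utter <- function(speaker_rep) {
  if (length(speaker_rep) == 0L) stop("invariant violation: empty repertoire")
  speaker_rep <- mask_to_langs(langs_to_mask(speaker_rep))
  if (length(speaker_rep) == 1L) return(speaker_rep)
  speaker_rep[sample.int(length(speaker_rep), 1L)]
}

#' Creolization rule
#'
#' A hearer whose repertoire contains both the substrate A and the lexifier
#' E (with or without C) replaces it, with probability \code{gamma}, by the
#' creole alone: \code{{C}}. Otherwise the repertoire is unchanged.
#'
#' @param rep Character repertoire.
#' @param gamma Creolization probability.
#' @return The (possibly creolized) repertoire.
#' @examples
#' creolization_check(c("A", "E"), gamma = 1)  # "C"
#' @export
creolization_check <- function(rep, gamma) {
  mask <- langs_to_mask(rep)
  if (bitwAnd(mask, 3L) == 3L && stats::runif(1) < gamma)
    return("C")
  mask_to_langs(mask)
}

#' Apply one speaker/hearer interaction
#'
#' Naming-Game rules with delta-gated substrate intelligibility: (a) if the
#' hearer does not hold the uttered language she learns it (adds it to her
#' repertoire); (b) if she does, the exchange succeeds -- always for E or C,
#' with probability \code{delta} for A -- and on success both repertoires
#' collapse to the uttered language. After the interaction the creolization
#' rule is applied to the hearer.
#'
#' @param state An \code{ng_state}.
#' @param speaker,hearer Agent references as returned by
#'   \code{\link{draw_pair}} (a \code{list(group, index)} with group one of
#'   \code{"EU"}, \code{"M"}, \code{"B"}).
#' @param uttered Language label, a member of the speaker's repertoire.
#' @param params An \code{ng_params}.
#' @return \code{list(state, outcome)} where \code{outcome} records the
#'   groups, the utterance, the result (\code{"learned"}, \code{"success"}
#'   or \code{"failed_A"}) and whether the hearer creolized.
#' @export
apply_interaction <- function(state, speaker, hearer, uttered, params) {
  stopifnot(inherits(state, "ng_state"))
  stopifnot_params(params)
  if (hearer$group == "EU")
    stop("topology violation: Europeans never act as hearers")
  s <- get_mask(state, speaker)
  h <- get_mask(state, hearer)
  l <- .lang_bits[[uttered]]
  if (bitwAnd(s, l) == 0L)
    stop("utterance must belong to the speaker's repertoire")
  h_new <- h; s_new <- s
  if (bitwAnd(h, l) == 0L) {
    h_new <- bitwOr(h, l)
    result <- "learned"
  } else if (l == 2L && stats::runif(1) >= params$delta) {
    result <- "failed_A"
  } else {
    h_new <- l; s_new <- l
    result <- "success"
  }
  creolized <- FALSE
  if (bitwAnd(h_new, 3L) == 3L &&
      (!params$creolize_only_on_change || h_new != h)) {
    if (stats::runif(1) < params$gamma) {
      h_new <- 4L
      creolized <- TRUE
    }
  }
  state <- set_mask(state, hearer, h_new)
  if (speaker$group != "EU" && s_new != s)
    state <- set_mask(state, speaker, s_new)
  list(state = state,
       outcome = list(speaker_group = speaker$group,
                      hearer_group = hearer$group,
                      uttered = uttered, result = result,
                      creolized = creolized))
}

#' Advance the dynamics by one counted step
#'
#' Draws a pair, performs the utterance and interaction, and applies the
#' creolization rule; epsilon-rejected draws are counted null steps. This is
#' the plain-R step used for tiny populations and validation; long runs go
#' through \code{\link{run_game}}.
#'
#' @inheritParams draw_pair
#' @return \code{list(state, outcome)}; \code{outcome$result} is
#'   \code{"null_step"} when nothing happened.
#' @export
step_game <- function(state, params) {
  pair <- draw_pair(state, params)
  if (pair$null_step) {
    state$interactions_elapsed <- state$interactions_elapsed + 1
    return(list(state = state,
                outcome = list(result = "null_step", creolized = FALSE)))
  }
  l <- utter(mask_to_langs(get_mask(state, pair$speaker)))
  res <- apply_interaction(state, pair$speaker, pair$hearer, l, params)
  res$state$interactions_elapsed <- res$state$interactions_elapsed + 1
  res
}
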