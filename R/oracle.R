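# Exact Markov-chain companion to the stochastic engine for tiny
# populations. Agents of the same group holding the same repertoire are
# exchangeable, so a chain state is a pair of multisets (one per group) over
# the 7 possible repertoires; the transition matrix enumerates every
# (pair draw, role assignment, epsilon gate, utterance, delta draw, gamma
# draw) outcome exactly, under the same rule variants as the simulator.

# repertoire types, as bitmasks: {E},{A},{C},{A,E},{E,C},{A,C},{A,E,C}
.type_masks <- c(1L, 2L, 4L, 3L, 5L, 6L, 7L)

# all length-7 non-negative integer vectors summing to n (multisets of size
# n over the 7 repertoire types)
.compositions7 <- function(n) {
  if (n == 0L) return(matrix(0L, 1L, 7L))
  rec <- function(n, k) {
    if (k == 1L) return(matrix(n, 1L, 1L))
    do.call(rbind, lapply(0:n, function(i) cbind(i, rec(n - i, k - 1L))))
  }
  unname(rec(as.integer(n), 7L))
}

state_key <- function(m, b) paste(c(m, b), collapse = ",")

#' Enumerate the exact chain's state space
#'
#' @param n_m,n_b Mulatto and Bozal counts (small; the product of multiset
#'   counts is capped at 1e5 states).
#' @return A list of states, each \code{list(m, b)} of length-7 count
#'   vectors over the repertoire types
#'   \code{{E},{A},{C},{A,E},{E,C},{A,C},{A,E,C}}.
#' @export
enumerate_states <- function(n_m, n_b) {
  if (n_m + n_b < 1) stop("need at least one Mulatto or Bozal agent")
  n_states <- choose(n_m + 6, 6) * choose(n_b + 6, 6)
  if (n_states > 1e5)
    stop(sprintf("state space too large (%g states; guard is 1e5)", n_states))
  ms <- .compositions7(n_m)
  bs <- .compositions7(n_b)
  out <- vector("list", nrow(ms) * nrow(bs))
  k <- 0L
  for (i in seq_len(nrow(ms)))
    for (j in seq_len(nrow(bs))) {
      k <- k + 1L
      out[[k]] <- list(m = ms[i, ], b = bs[j, ])
    }
  out
}

# distribution of (speaker', hearer') repertoires after one interaction,
# given speaker mask s and hearer mask h; returns matrix cols (s2, h2, p)
interaction_outcome_dist <- function(s, h, gamma, delta, strict) {
  rows <- list()
  add <- function(s2, h2, p) rows[[length(rows) + 1L]] <<- c(s2, h2, p)
  langs <- c(1L, 2L, 4L)[bitwAnd(s, c(1L, 2L, 4L)) != 0L]
  pl <- 1 / length(langs)
  for (l in langs) {
    if (bitwAnd(h, l) == 0L) {
      branches <- list(c(s, bitwOr(h, l), pl))                 # learning
    } else if (l == 2L) {
      branches <- list(c(2L, 2L, pl * delta),                  # A success
                       c(s, h, pl * (1 - delta)))              # A failure
    } else {
      branches <- list(c(l, l, pl))                            # E/C success
    }
    for (br in branches) {
      s1 <- br[1]; h1 <- br[2]; pb <- br[3]
      if (pb == 0) next
      if (bitwAnd(h1, 3L) == 3L && (!strict || h1 != h)) {
        if (gamma > 0) add(s1, 4L, pb * gamma)
        if (gamma < 1) add(s1, h1, pb * (1 - gamma))
      } else {
        add(s1, h1, pb)
      }
    }
  }
  do.call(rbind, rows)
}

#' Build the exact one-step transition matrix
#'
#' Transcribes the interaction rules into a row-stochastic matrix over the
#' state space of \code{\link{enumerate_states}}, honouring the same
#' configuration switches (\code{eps_null_advances_time},
#' \code{creolize_only_on_change}) as the simulator so that
#' simulation/oracle comparisons are exact like-for-like.
#'
#' @param n_eu,n_m,n_b Group sizes.
#' @param params An \code{ng_params}.
#' @return An object of class \code{ng_chain}: \code{states}, row-stochastic
#'   \code{P}, the index \code{all_e} of the absorbing all-E state, and the
#'   configuration used.
#' @export
build_transition_matrix <- function(n_eu, n_m, n_b, params) {
  stopifnot_params(params)
  states <- enumerate_states(n_m, n_b)
  n_states <- length(states)
  keys <- vapply(states, function(s) state_key(s$m, s$b), character(1))
  idx <- stats::setNames(seq_len(n_states), keys)
  N <- n_eu + n_m + n_b
  eps <- params$epsilon
  strict <- params$creolize_only_on_change
  eps_adv <- params$eps_null_advances_time

  # cache per (s, h) outcome distributions: 7x7 masks + Eu speaker (s = 1)
  odist <- new.env(hash = TRUE)
  get_dist <- function(s, h) {
    k <- paste(s, h)
    d <- odist[[k]]
    if (is.null(d)) {
      d <- interaction_outcome_dist(s, h, params$gamma, params$delta, strict)
      odist[[k]] <- d
    }
    d
  }

  P <- matrix(0, n_states, n_states)
  for (si in seq_len(n_states)) {
    st <- states[[si]]
    m <- st$m; b <- st$b
    # interaction events: list of (prob, sg, st_type, hg, ht_type)
    events <- list()
    null_mass <- 0
    add_ev <- function(p, sg, stt, hg, htt) {
      if (p > 0)
        events[[length(events) + 1L]] <<- list(p = p, sg = sg, st = stt,
                                               hg = hg, ht = htt)
    }
    # unordered-pair weights, Eu-Eu pairs excluded (discarded and redrawn)
    w_eu_m <- n_eu * m
    w_eu_b <- n_eu * b
    w_tot <- choose(N, 2) - choose(n_eu, 2)
    if (!eps_adv) w_tot <- w_tot - (1 - eps) * sum(w_eu_b)
    scale_eu_b <- if (eps_adv) 1 else eps
    for (t in 1:7) {
      if (w_eu_m[t] > 0) add_ev(w_eu_m[t] / w_tot, "EU", 0L, "M", t)
      if (w_eu_b[t] > 0) {
        p_pair <- w_eu_b[t] * scale_eu_b / w_tot
        if (eps_adv) {
          null_mass <- null_mass + p_pair * (1 - eps)
          add_ev(p_pair * eps, "EU", 0L, "B", t)
        } else {
          add_ev(p_pair, "EU", 0L, "B", t)
        }
      }
    }
    for (t1 in 1:7) for (t2 in t1:7) {
      # within-group M pairs
      cnt <- if (t1 == t2) m[t1] * (m[t1] - 1) / 2 else m[t1] * m[t2]
      if (cnt > 0) {
        p <- cnt / w_tot
        if (t1 == t2) add_ev(p, "M", t1, "M", t1)
        else { add_ev(p / 2, "M", t1, "M", t2); add_ev(p / 2, "M", t2, "M", t1) }
      }
      # within-group B pairs
      cnt <- if (t1 == t2) b[t1] * (b[t1] - 1) / 2 else b[t1] * b[t2]
      if (cnt > 0) {
        p <- cnt / w_tot
        if (t1 == t2) add_ev(p, "B", t1, "B", t1)
        else { add_ev(p / 2, "B", t1, "B", t2); add_ev(p / 2, "B", t2, "B", t1) }
      }
    }
    for (t1 in 1:7) for (t2 in 1:7) {
      cnt <- m[t1] * b[t2]
      if (cnt > 0) {
        p <- cnt / w_tot
        add_ev(p / 2, "M", t1, "B", t2)
        add_ev(p / 2, "B", t2, "M", t1)
      }
    }
    if (null_mass > 0) P[si, si] <- P[si, si] + null_mass
    for (ev in events) {
      s_mask <- if (ev$sg == "EU") 1L else .type_masks[ev$st]
      h_mask <- .type_masks[ev$ht]
      d <- get_dist(s_mask, h_mask)
      for (r in seq_len(nrow(d))) {
        s2 <- d[r, 1]; h2 <- d[r, 2]; po <- d[r, 3]
        m2 <- m; b2 <- b
        # hearer move
        hti <- ev$ht; h2i <- match(h2, .type_masks)
        if (ev$hg == "M") { m2[hti] <- m2[hti] - 1L; m2[h2i] <- m2[h2i] + 1L }
        else              { b2[hti] <- b2[hti] - 1L; b2[h2i] <- b2[h2i] + 1L }
        # speaker move (non-European speakers can collapse on success)
        if (ev$sg != "EU" && s2 != s_mask) {
          sti <- ev$st; s2i <- match(s2, .type_masks)
          if (ev$sg == "M") { m2[sti] <- m2[sti] - 1L; m2[s2i] <- m2[s2i] + 1L }
          else              { b2[sti] <- b2[sti] - 1L; b2[s2i] <- b2[s2i] + 1L }
        }
        ti <- idx[[state_key(m2, b2)]]
        P[si, ti] <- P[si, ti] + ev$p * po
      }
    }
  }
  rs <- rowSums(P)
  if (any(abs(rs - 1) > 1e-12))
    stop(sprintf("internal consistency error: row sums deviate up to %g",
                 max(abs(rs - 1))))
  all_e_key <- state_key(c(n_m, rep(0L, 6)), c(n_b, rep(0L, 6)))
  structure(list(states = states, P = P, idx = idx,
                 all_e = unname(idx[[all_e_key]]),
                 n_eu = n_eu, n_m = n_m, n_b = n_b, params = params),
            class = "ng_chain")
}

# map an ng_state (or list(m, b) of count vectors, or NULL for the standard
# initial condition) to a chain state index
chain_state_index <- function(model, start = NULL) {
  if (is.null(start)) {
    m <- c(model$n_m, rep(0L, 6))      # all Mulattos {E}
    b <- c(0L, model$n_b, rep(0L, 5))  # all Bozals {A}
  } else if (inherits(start, "ng_state")) {
    m <- tabulate(match(start$rep_m, .type_masks), 7L)
    b <- tabulate(match(start$rep_b, .type_masks), 7L)
  } else {
    m <- start$m; b <- start$b
  }
  i <- model$idx[[state_key(m, b)]]
  if (is.null(i)) stop("start state not in the chain's state space")
  unname(i)
}

#' Exact probability of all-E absorption
#'
#' For a finite horizon, iterates the transition matrix (matrix-vector
#' products, robust for near-absorbing chains) and reads off the occupancy
#' of the all-E state; for \code{horizon = Inf}, solves the linear
#' absorption system on the states from which all-E is reachable (states
#' that cannot reach it get probability 0 -- e.g. creole-locked populations
#' without Europeans).
#'
#' @param model An \code{ng_chain} from \code{\link{build_transition_matrix}}.
#' @param start Start state: \code{NULL} for the standard initial condition
#'   (Mulattos \code{{E}}, Bozals \code{{A}}), an \code{ng_state}, or a
#'   \code{list(m, b)} of type-count vectors.
#' @param horizon Number of counted interactions, or \code{Inf}.
#' @return The absorption probability.
#' @export
absorption_probability <- function(model, start = NULL, horizon = Inf) {
  stopifnot(inherits(model, "ng_chain"))
  s0 <- chain_state_index(model, start)
  P <- model$P
  n <- nrow(P)
  if (is.finite(horizon)) {
    v <- numeric(n); v[s0] <- 1
    for (t in seq_len(horizon)) v <- v %*% P
    return(as.numeric(v[model$all_e]))
  }
  # reverse reachability from the absorbing all-E state
  adj <- P > 0
  reach <- logical(n); reach[model$all_e] <- TRUE
  frontier <- model$all_e
  while (length(frontier)) {
    preds <- which(rowSums(adj[, frontier, drop = FALSE]) > 0 & !reach)
    reach[preds] <- TRUE
    frontier <- preds
  }
  p <- numeric(n)
  p[model$all_e] <- 1
  trans <- setdiff(which(reach), model$all_e)
  if (length(trans)) {
    A <- diag(length(trans)) - P[trans, trans, drop = FALSE]
    sol <- tryCatch(solve(A, P[trans, model$all_e]),
                    error = function(e)
                      stop("absorption limit computation failed: ",
                           conditionMessage(e)))
    p[trans] <- sol
  }
  unname(p[s0])
}

#' Exact one-step state distribution
#'
#' @param model An \code{ng_chain}.
#' @param start As in \code{\link{absorption_probability}}.
#' @return Named probability vector over state keys after one counted step.
#' @export
one_step_distribution <- function(model, start = NULL) {
  s0 <- chain_state_index(model, start)
  stats::setNames(model$P[s0, ], names(model$idx))
}
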