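#' Run the Naming-Game dynamics to its asymptotic regime
#'
#' Iterates the pairwise dynamics for
#' \code{max_interactions_per_agent * (n_m + n_b)} counted interactions
#' (compiled loop), stopping early if the all-E configuration is reached --
#' the only absorbing state, since Europeans keep injecting E so an all-C
#' population is merely quasi-stationary. The asymptotic summary is the
#' time-average of the language fractions over the final
#' \code{tail_window_fraction} of the run; on early all-E absorption the
#' remainder of the window is filled at \code{f_E = 1}, its exact value.
#'
#' @param state An \code{ng_state}, freshly initialized or resumed.
#' @param params An \code{ng_params}. If \code{params$seed} is non-NULL the
#'   run is reproducible and the caller's RNG state is restored afterwards.
#' @param n_trajectory_points If positive, also record roughly this many
#'   equally spaced snapshots of the instantaneous fractions.
#' @return A list with \code{state} (final), \code{summary} (tail-averaged
#'   named fractions \code{c(E, A, C)}), \code{absorbed_all_E},
#'   \code{creolizations} (number of creolization events) and, when
#'   requested, \code{trajectory} (a data frame).
#' @examples
#' p <- model_params(seed = 1, max_interactions_per_agent = 200)
#' st <- init_population(n_eu = 10, n_m = 5, n_b = 85)
#' run_game(st, p)$summary
#' @export
run_game <- function(state, params, n_trajectory_points = 0) {
  stopifnot(inherits(state, "ng_state"))
  stopifnot_params(params)
  res <- with_seed(params$seed,
    ng_run_cpp(state$n_eu, state$rep_m, state$rep_b,
               params$gamma, params$delta, params$epsilon,
               params$max_interactions_per_agent,
               params$tail_window_fraction,
               params$creolize_only_on_change,
               params$eps_null_advances_time,
               as.integer(n_trajectory_points)))
  final <- state
  final$rep_m <- res$rep_m
  final$rep_b <- res$rep_b
  final$interactions_elapsed <- state$interactions_elapsed + res$interactions
  # incremental weight bookkeeping can leave |error| ~ 1e-15 around 0 and 1
  summ <- c(E = res$f_E, A = res$f_A, C = res$f_C)
  summ[summ < 0] <- 0
  summ[summ > 1] <- 1
  out <- list(state = final,
              summary = summ,
              absorbed_all_E = res$absorbed_all_E,
              creolizations = res$creolizations)
  if (n_trajectory_points > 0) out$trajectory <- res$trajectory
  out
}

#' Replicate runs at a fixed demography
#'
#' Runs \code{n_replicates} independent simulations from the standard
#' initial condition; replicate \code{r} uses seed \code{seed + r}.
#'
#' @param n_eu,n_m,n_b Group sizes.
#' @param params An \code{ng_params} (its own \code{seed} entry is ignored).
#' @param n_replicates Number of replicates.
#' @param seed Base integer seed.
#' @return Data frame with one row per replicate: \code{f_E}, \code{f_A},
#'   \code{f_C}, \code{absorbed_all_E}.
#' @export
replicate_runs <- function(n_eu, n_m, n_b, params, n_replicates, seed) {
  stopifnot_params(params)
  rows <- lapply(seq_len(n_replicates), function(r) {
    p <- params
    p$seed <- as.integer(seed + r)
    res <- run_game(init_population(n_eu, n_m, n_b), p)
    data.frame(replicate = r,
               f_E = res$summary[["E"]], f_A = res$summary[["A"]],
               f_C = res$summary[["C"]],
               absorbed_all_E = res$absorbed_all_E)
  })
  do.call(rbind, rows)
}
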