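#' Model parameters for the contact-language Naming Game
#'
#' Bundles and validates the parameters governing the three-population
#' dynamics: the creolization probability \code{gamma} (a hearer holding both
#' the lexifier E and the substrate A replaces her repertoire with the creole
#' C), the African mutual-intelligibility probability \code{delta} (two
#' A-utterance exchanges succeed only with this probability, coarse-graining
#' substrate multilingualism), and the segregation parameter \code{epsilon}
#' (a drawn European--Bozal pair actually interacts only with this
#' probability).
#'
#' @param gamma Creolization probability in \[0, 1\].
#' @param delta Probability that an A utterance is understood by a hearer who
#'   already holds A, in \[0, 1\].
#' @param epsilon Probability that a drawn European--Bozal pair interacts,
#'   in \[0, 1\].
#' @param dominance_threshold Fraction in (0, 1\]; a language dominates a run
#'   when its tail-averaged fraction among Mulattos+Bozals exceeds it.
#' @param max_interactions_per_agent Run length: total interactions equal
#'   this value times the number of Mulatto+Bozal agents.
#' @param tail_window_fraction Fraction in (0, 1) of the run, at its end,
#'   over which language fractions are time-averaged.
#' @param creolize_only_on_change If \code{TRUE}, the creolization draw is
#'   attempted only when the hearer's repertoire changed in the interaction;
#'   the default applies it after every interaction the hearer takes part in.
#' @param eps_null_advances_time If \code{TRUE} (default) an
#'   epsilon-rejected European--Bozal draw is a counted null step; if
#'   \code{FALSE} it is discarded and redrawn, which rescales time but not
#'   the asymptotic state.
#' @param seed Optional integer seed; \code{NULL} leaves the RNG state alone.
#'
#' @return An object of class \code{ng_params}.
#' @examples
#' p <- model_params(gamma = 0.8, delta = 0.1, epsilon = 0.06)
#' p
#' @export
model_params <- function(gamma = 0.8, delta = 0.1, epsilon = 0.06,
                         dominance_threshold = 0.8,
                         max_interactions_per_agent = 2000,
                         tail_window_fraction = 0.1,
                         creolize_only_on_change = FALSE,
                         eps_null_advances_time = TRUE,
                         seed = NULL) {
  for (nm in c("gamma", "delta", "epsilon")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(sprintf("'%s' must be a single probability in [0, 1]", nm))
  }
  if (!is.numeric(dominance_threshold) || dominance_threshold <= 0 ||
      dominance_threshold > 1)
    stop("'dominance_threshold' must lie in (0, 1]")
  if (!is.numeric(max_interactions_per_agent) ||
      max_interactions_per_agent < 1)
    stop("'max_interactions_per_agent' must be >= 1")
  if (!is.numeric(tail_window_fraction) || tail_window_fraction <= 0 ||
      tail_window_fraction >= 1)
    stop("'tail_window_fraction' must lie in (0, 1)")
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(gamma = gamma, delta = delta, epsilon = epsilon,
                 dominance_threshold = dominance_threshold,
                 max_interactions_per_agent = max_interactions_per_agent,
                 tail_window_fraction = tail_window_fraction,
                 creolize_only_on_change = isTRUE(creolize_only_on_change),
                 eps_null_advances_time = isTRUE(eps_null_advances_time),
                 seed = seed),
            class = "ng_params")
}

#' @export
print.ng_params <- function(x, ...) {
  cat("Naming-Game parameters\n")
  cat(sprintf("  gamma (creolization)        : %.3f\n", x$gamma))
  cat(sprintf("  delta (A intelligibility)   : %.3f\n", x$delta))
  cat(sprintf("  epsilon (Eu-B contact)      : %.3f\n", x$epsilon))
  cat(sprintf("  dominance threshold         : %.2f\n", x$dominance_threshold))
  cat(sprintf("  interactions per agent      : %g\n",
              x$max_interactions_per_agent))
  cat(sprintf("  tail window fraction        : %.2f\n",
              x$tail_window_fraction))
  if (x$creolize_only_on_change)
    cat("  creolization only after repertoire changes\n")
  if (!x$eps_null_advances_time)
    cat("  epsilon-rejected draws redrawn (no null steps)\n")
  invisible(x)
}

stopifnot_params <- function(params) {
  if (!inherits(params, "ng_params"))
    stop("'params' must be created with model_params()")
  invisible(params)
}

# Evaluate `expr` under a temporary seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
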