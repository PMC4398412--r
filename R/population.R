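# Repertoires are stored internally as bitmasks over {E = 1, A = 2, C = 4};
# the user-facing representation is a character vector such as c("E", "A").

.lang_bits <- c(E = 1L, A = 2L, C = 4L)

mask_to_langs <- function(mask) {
  names(.lang_bits)[bitwAnd(mask, .lang_bits) != 0L]
}

langs_to_mask <- function(langs) {
  if (length(langs) == 0L) stop("a repertoire must be non-empty")
  bad <- setdiff(langs, names(.lang_bits))
  if (length(bad)) stop("unknown language(s): ", paste(bad, collapse = ", "))
  sum(.lang_bits[unique(langs)])
}

#' Initialize a structured population
#'
#' Creates the starting configuration of the three-group contact ecology:
#' \code{n_eu} Europeans (an unchangeable source of the lexifier E, not
#' stored explicitly), \code{n_m} Mulattos starting with repertoire
#' \code{{E}}, and \code{n_b} Bozal slaves starting with \code{{A}}. Group
#' sizes are conserved for the whole run.
#'
#' @param n_eu,n_m,n_b Non-negative group sizes. At least one Mulatto or
#'   Bozal agent is required (Europeans never change language, so a
#'   population without M or B agents has no dynamics).
#' @param params Optional \code{\link{model_params}} object, attached to the
#'   state for convenience.
#' @return An object of class \code{ng_state}.
#' @examples
#' st <- init_population(n_eu = 2, n_m = 1, n_b = 1)
#' repertoires(st)
#' @export
init_population <- function(n_eu, n_m, n_b, params = NULL) {
  for (v in list(n_eu, n_m, n_b))
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 ||
        v != round(v))
      stop("group sizes must be non-negative integers")
  n_eu <- as.integer(n_eu); n_m <- as.integer(n_m); n_b <- as.integer(n_b)
  if (n_eu + n_m + n_b == 0L) stop("invalid population: total size is zero")
  if (n_m + n_b == 0L)
    stop("invalid population: no Mulatto or Bozal agents (no possible hearers)")
  structure(list(n_eu = n_eu, n_m = n_m, n_b = n_b,
                 rep_m = rep(1L, n_m),    # {E}
                 rep_b = rep(2L, n_b),    # {A}
                 interactions_elapsed = 0,
                 params = params),
            class = "ng_state")
}

#' Query agent repertoires
#'
#' @param state An \code{ng_state}.
#' @param group One of \code{"EU"}, \code{"M"}, \code{"B"}, or \code{NULL}
#'   for all Mulatto and Bozal agents.
#' @param index Optional agent index within the group.
#' @return A list of character repertoires, or a single character vector if
#'   \code{index} is given. Every European repertoire is exactly
#'   \code{"E"}.
#' @export
repertoires <- function(state, group = NULL, index = NULL) {
  stopifnot(inherits(state, "ng_state"))
  get_one <- function(masks, i) mask_to_langs(masks[i])
  if (!is.null(group) && group == "EU") {
    if (!is.null(index)) {
      if (index < 1 || index > state$n_eu) stop("European index out of range")
      return("E")
    }
    return(rep(list("E"), state$n_eu))
  }
  masks <- switch(if (is.null(group)) "ALL" else group,
                  M = state$rep_m, B = state$rep_b,
                  ALL = c(state$rep_m, state$rep_b),
                  stop("unknown group"))
  if (!is.null(index)) {
    if (index < 1 || index > length(masks)) stop("agent index out of range")
    return(mask_to_langs(masks[index]))
  }
  lapply(masks, mask_to_langs)
}

#' @export
print.ng_state <- function(x, ...) {
  cat(sprintf("Population state: %d Europeans, %d Mulattos, %d Bozals\n",
              x$n_eu, x$n_m, x$n_b))
  cat(sprintf("  interactions elapsed: %g\n", x$interactions_elapsed))
  f <- measure_fractions(x)
  cat(sprintf("  current fractions (M+B): E %.3f  A %.3f  C %.3f\n",
              f["E"], f["A"], f["C"]))
  invisible(x)
}

#' Language fractions among Mulattos and Bozals
#'
#' Each Mulatto or Bozal agent contributes weight \code{1/|repertoire|} to
#' every language she currently holds, so the three fractions sum to one.
#' Europeans are excluded: the quantity of interest is which language the
#' non-European population ends up speaking.
#'
#' @param state An \code{ng_state}.
#' @return Named numeric vector \code{c(E, A, C)}.
#' @examples
#' st <- init_population(1, 1, 1)
#' measure_fractions(st)  # E 0.5, A 0.5, C 0
#' @export
measure_fractions <- function(state) {
  stopifnot(inherits(state, "ng_state"))
  masks <- c(state$rep_m, state$rep_b)
  if (length(masks) == 0L)
    stop("invalid population: no Mulatto or Bozal agents")
  sizes <- vapply(masks, function(m) length(mask_to_langs(m)), integer(1))
  w <- 1 / sizes
  out <- c(E = sum(w[bitwAnd(masks, 1L) != 0L]),
           A = sum(w[bitwAnd(masks, 2L) != 0L]),
           C = sum(w[bitwAnd(masks, 4L) != 0L])) / length(masks)
  out
}
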