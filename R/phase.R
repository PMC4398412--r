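# Demographic plane: x = N_M / (N_M + N_B), the Mulatto share of the Black
# population; y = (N_M + N_B) / N, the Black share of the total population.

#' Construct a demographic point
#'
#' @param x Mulatto fraction of the Black population, in \[0, 1\].
#' @param y Black fraction of the total population, in (0, 1\].
#' @return An object of class \code{demographic_point}.
#' @export
demographic_point <- function(x, y) {
  if (!is.numeric(x) || is.na(x) || x < 0 || x > 1)
    stop("'x' must lie in [0, 1]")
  if (!is.numeric(y) || is.na(y) || y <= 0 || y > 1)
    stop("'y' must lie in (0, 1]; y = 0 means no Black population and the ",
         "Mulatto fraction is undefined")
  structure(list(x = x, y = y), class = "demographic_point")
}

#' Convert a demographic point to integer group sizes
#'
#' Integerization is round-half-up on the Black total, then on the Mulatto
#' count; when \code{y < 1} at least one European is kept (the Black total
#' is rounded down if needed).
#'
#' @param point A \code{\link{demographic_point}} (or \code{list(x, y)}).
#' @param n_total Total population size N.
#' @return Named integer vector \code{c(n_eu, n_m, n_b)} summing to
#'   \code{n_total}.
#' @examples
#' point_to_counts(demographic_point(0.05, 0.9), 1000)
#' @export
point_to_counts <- function(point, n_total) {
  if (n_total < 2) stop("'n_total' must be at least 2")
  x <- point$x; y <- point$y
  half_up <- function(v) floor(v + 0.5)
  n_black <- half_up(y * n_total)
  if (y < 1 && n_black >= n_total) n_black <- n_total - 1
  n_m <- half_up(x * n_black)
  n_b <- n_black - n_m
  n_eu <- n_total - n_black
  if (n_m + n_b == 0)
    stop("invalid point: no Mulatto or Bozal agents at this resolution")
  c(n_eu = as.integer(n_eu), n_m = as.integer(n_m), n_b = as.integer(n_b))
}

#' Estimate dominance probabilities at one demographic point
#'
#' Runs replicate simulations at the demography implied by \code{point} and
#' \code{n_total} and reports the fraction of replicates in which the creole
#' (resp. the European language) dominates, i.e. its tail-averaged fraction
#' among Mulattos+Bozals exceeds \code{params$dominance_threshold}.
#'
#' @param point A \code{\link{demographic_point}}.
#' @param params An \code{ng_params}.
#' @param n_total Total population size.
#' @param n_replicates Replicates (seeds \code{seed + 1 .. seed + n}).
#' @param seed Base seed.
#' @return One-row data frame: \code{x}, \code{y}, \code{p_creole},
#'   \code{p_european}, mean \code{f_E}, \code{f_A}, \code{f_C},
#'   \code{n_replicates}.
#' @export
estimate_dominance <- function(point, params, n_total, n_replicates = 10,
                               seed = 1L) {
  stopifnot_params(params)
  cnt <- point_to_counts(point, n_total)
  reps <- replicate_runs(cnt[["n_eu"]], cnt[["n_m"]], cnt[["n_b"]],
                         params, n_replicates, seed)
  th <- params$dominance_threshold
  data.frame(x = point$x, y = point$y,
             p_creole = mean(reps$f_C > th),
             p_european = mean(reps$f_E > th),
             f_E = mean(reps$f_E), f_A = mean(reps$f_A),
             f_C = mean(reps$f_C),
             n_replicates = n_replicates)
}

#' Sweep a grid of demographic points
#'
#' @param xs,ys Grid coordinates (fractions).
#' @param params An \code{ng_params}.
#' @inheritParams estimate_dominance
#' @return Data frame with one row per valid grid point (invalid points --
#'   e.g. y so small that no Black agents remain -- are skipped with a
#'   warning).
#' @export
sweep_grid <- function(xs, ys, params, n_total, n_replicates = 10,
                       seed = 1L) {
  stopifnot_params(params)
  if (length(xs) == 0 || length(ys) == 0) stop("empty grid")
  rows <- list()
  k <- 0L
  for (yi in seq_along(ys)) for (xi in seq_along(xs)) {
    k <- k + 1L
    pt <- tryCatch(demographic_point(xs[xi], ys[yi]), error = identity)
    est <- if (inherits(pt, "error")) pt else
      tryCatch(estimate_dominance(pt, params, n_total, n_replicates,
                                  seed + (k - 1L) * (n_replicates + 1L)),
               error = identity)
    if (inherits(est, "error")) {
      warning(sprintf("skipping grid point (x=%g, y=%g): %s",
                      xs[xi], ys[yi], conditionMessage(est)))
    } else {
      rows[[length(rows) + 1L]] <- est
    }
  }
  do.call(rbind, rows)
}

#' Locate the creole/no-creole transition by bisection
#'
#' For each \code{x}, finds the Black-population fraction \code{y*} at which
#' the replicate-estimated creole-dominance probability crosses 0.5,
#' bisecting in \code{y} to within \code{y_tolerance}. Where the
#' probability does not bracket 0.5 between the \code{y_range} endpoints
#' (e.g. \code{x = 1}, where no Bozals exist and the creole can never
#' emerge) the curve is reported as \code{NA}.
#'
#' @param params An \code{ng_params}.
#' @param xs Vector of x values.
#' @param n_total Total population size.
#' @param n_replicates Replicates per probability evaluation.
#' @param y_tolerance Bisection stopping width in y.
#' @param seed Base seed.
#' @param y_range Search interval for y.
#' @return Data frame \code{x}, \code{y_star} (NA where undefined).
#' @export
transition_curve <- function(params, xs, n_total, n_replicates = 10,
                             y_tolerance = 0.02, seed = 1L,
                             y_range = c(0.05, 0.99)) {
  stopifnot_params(params)
  eval_ctr <- 0L
  p_creole_at <- function(x, y) {
    eval_ctr <<- eval_ctr + 1L
    est <- estimate_dominance(demographic_point(x, y), params, n_total,
                              n_replicates,
                              seed + eval_ctr * (n_replicates + 1L))
    est$p_creole
  }
  y_star <- vapply(xs, function(x) {
    lo <- y_range[1]; hi <- y_range[2]
    p_lo <- p_creole_at(x, lo)
    p_hi <- p_creole_at(x, hi)
    if (!(p_lo < 0.5 && p_hi >= 0.5)) {
      message(sprintf(
        "transition undefined at x=%g (p_creole %0.2f at y=%g, %0.2f at y=%g)",
        x, p_lo, lo, p_hi, hi))
      return(NA_real_)
    }
    while (hi - lo > y_tolerance) {
      mid <- (lo + hi) / 2
      if (p_creole_at(x, mid) >= 0.5) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
  data.frame(x = xs, y_star = y_star)
}

#' Build the epsilon-bounded transition stripe
#'
#' Computes the transition curve at \code{epsilons} (defaults 0.05, 0.06,
#' 0.07, sharing all other parameters), giving the lower, mid and upper
#' curves of the uncertainty stripe between predicted-creole (above) and
#' predicted-European (below) demographies. The same base seed is used for
#' every epsilon (common random numbers), which sharpens the between-epsilon
#' comparison.
#'
#' @inheritParams transition_curve
#' @param epsilons Three increasing contact probabilities.
#' @return A \code{transition_stripe}: data frame \code{x}, \code{y_lower},
#'   \code{y_mid}, \code{y_upper} with the generating settings as
#'   attributes.
#' @export
build_stripe <- function(params, xs, n_total, n_replicates = 10,
                         y_tolerance = 0.02, seed = 1L,
                         epsilons = c(0.05, 0.06, 0.07),
                         y_range = c(0.05, 0.99)) {
  stopifnot_params(params)
  if (length(epsilons) != 3 || is.unsorted(epsilons))
    stop("'epsilons' must be three increasing values")
  curves <- lapply(epsilons, function(e) {
    p <- params; p$epsilon <- e
    transition_curve(p, xs, n_total, n_replicates, y_tolerance, seed,
                     y_range)$y_star
  })
  out <- data.frame(x = xs, y_lower = curves[[1]], y_mid = curves[[2]],
                    y_upper = curves[[3]])
  structure(out,
            class = c("transition_stripe", "data.frame"),
            params = params, n_total = n_total,
            n_replicates = n_replicates, y_tolerance = y_tolerance,
            seed = seed, epsilons = epsilons)
}

#' Interpolate a stripe at given x values
#'
#' Linear interpolation between tabulated x values; outside the tabulated
#' range the nearest defined endpoint is used, with a warning.
#'
#' @param stripe A \code{transition_stripe} (or any data frame with columns
#'   \code{x}, \code{y_lower}, \code{y_mid}, \code{y_upper}).
#' @param x Numeric vector of query points.
#' @return Data frame \code{x}, \code{y_lower}, \code{y_mid},
#'   \code{y_upper}.
#' @export
stripe_at <- function(stripe, x) {
  warned <- FALSE
  interp <- function(col) {
    ok <- !is.na(stripe$x) & !is.na(stripe[[col]])
    if (sum(ok) == 0) stop("stripe has no defined points in column ", col)
    xr <- range(stripe$x[ok])
    if (!warned && any(x < xr[1] | x > xr[2])) {
      warned <<- TRUE
      warning(sprintf(
        "x outside tabulated stripe range [%g, %g]; using nearest endpoint",
        xr[1], xr[2]))
    }
    if (sum(ok) == 1) return(rep(stripe[[col]][ok], length(x)))
    stats::approx(stripe$x[ok], stripe[[col]][ok], xout = x, rule = 2)$y
  }
  data.frame(x = x, y_lower = interp("y_lower"), y_mid = interp("y_mid"),
             y_upper = interp("y_upper"))
}

#' Write / read a transition stripe as CSV
#'
#' The CSV carries a provenance header (\code{#} comment lines recording
#' the generating parameters and seed) followed by the
#' \code{x, y_lower, y_mid, y_upper} table.
#'
#' @param stripe A \code{transition_stripe}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_stripe_csv <- function(stripe, path) {
  p <- attr(stripe, "params")
  hdr <- c("# creolegame transition stripe",
           if (!is.null(p))
             sprintf("# gamma=%g delta=%g N=%s replicates=%s seed=%s epsilons=%s",
                     p$gamma, p$delta,
                     format(attr(stripe, "n_total")),
                     format(attr(stripe, "n_replicates")),
                     format(attr(stripe, "seed")),
                     paste(attr(stripe, "epsilons"), collapse = ",")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(as.data.frame(stripe), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stripe_csv
#' @export
read_stripe_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("x", "y_lower", "y_mid", "y_upper")
  if (!all(need %in% names(df)))
    stop("stripe CSV must have columns ", paste(need, collapse = ", "))
  structure(df[need], class = c("transition_stripe", "data.frame"))
}
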