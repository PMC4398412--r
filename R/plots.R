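# Figures: the demographic plane with the transition stripe (optionally
# overlaying census points) and dominance surfaces from grid sweeps.

# the horizontal axis of the stripe figure is expanded by a power 0.2,
# which spreads out the small Mulatto fractions where the action is
power02_trans <- function() {
  scales::trans_new("power02", function(x) x^0.2, function(x) x^5,
                    domain = c(0, Inf))
}

#' Plot a transition stripe, optionally with demographic points
#'
#' Draws the uncertainty stripe between the lower and upper transition
#' curves (shaded), the mid curve (dashed), and, if given, classified or
#' labelled points. The x axis is expanded by a power 0.2 so that the
#' low-Mulatto-fraction region is readable.
#'
#' @param stripe A \code{transition_stripe}.
#' @param points Optional data frame with \code{x}, \code{y} and optionally
#'   \code{verdict} or \code{creole_observed} (used for colouring).
#' @param power_axis Apply the power-0.2 x-axis expansion (default TRUE).
#' @return A ggplot object.
#' @export
plot_stripe <- function(stripe, points = NULL, power_axis = TRUE) {
  df <- as.data.frame(stripe)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$y_lower,
                                      ymax = .data$y_upper),
                         fill = "grey70", alpha = 0.7) +
    ggplot2::geom_line(ggplot2::aes(y = .data$y_lower), colour = "black") +
    ggplot2::geom_line(ggplot2::aes(y = .data$y_upper), colour = "black") +
    ggplot2::geom_line(ggplot2::aes(y = .data$y_mid), colour = "black",
                       linetype = "dashed") +
    ggplot2::labs(x = "Mulatto fraction of Black population  N_M/(N_M+N_B)",
                  y = "Black fraction of population  (N_M+N_B)/N") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
  if (!is.null(points)) {
    colour_col <- if ("verdict" %in% names(points)) "verdict"
                  else if ("creole_observed" %in% names(points))
                    "creole_observed"
    if (is.null(colour_col)) {
      gg <- gg + ggplot2::geom_point(data = points,
                                     ggplot2::aes(y = .data$y))
    } else {
      gg <- gg +
        ggplot2::geom_point(data = points,
                            ggplot2::aes(y = .data$y,
                                         colour = .data[[colour_col]]),
                            size = 2)
    }
  }
  if (power_axis) gg <- gg + ggplot2::scale_x_continuous(trans = power02_trans())
  gg
}

#' Plot a dominance surface from a grid sweep
#'
#' @param grid Output of \code{\link{sweep_grid}}.
#' @param value Column to map to fill (default the creole fraction
#'   \code{"f_C"}; also useful: \code{"f_E"}, \code{"p_creole"}).
#' @return A ggplot object.
#' @export
plot_dominance_grid <- function(grid, value = "f_C") {
  if (!value %in% names(grid)) stop("no column '", value, "' in grid")
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$x, y = .data$y,
                                     fill = .data[[value]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "N_M/(N_M+N_B)", y = "(N_M+N_B)/N", fill = value) +
    ggplot2::theme_minimal()
}
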