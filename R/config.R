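# YAML run configuration shared by the command-line interface and scripted
# use. Validation is strict: unknown keys are rejected so that typos fail
# loudly instead of silently running with defaults.

.config_keys <- c(
  # model parameters
  "gamma", "delta", "epsilon", "dominance_threshold",
  "max_interactions_per_agent", "tail_window_fraction",
  "creolize_only_on_change", "eps_null_advances_time", "seed",
  # sweep / stripe settings
  "n_total", "n_replicates", "xs", "ys", "y_tolerance", "epsilons",
  "y_range",
  # io
  "out_dir", "column_aliases")

#' Read and validate a run configuration
#'
#' @param path YAML file. Keys mirror \code{\link{model_params}} plus sweep
#'   settings (\code{n_total}, \code{n_replicates}, \code{xs}, \code{ys},
#'   \code{y_tolerance}, \code{epsilons}, \code{y_range}) and io settings
#'   (\code{out_dir}, \code{column_aliases}). Unknown keys are an error.
#' @param overrides Named list applied on top of the file values (used by
#'   the CLI for flag overrides).
#' @return A validated list of class \code{run_config}.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (!is.list(cfg)) stop("configuration must be a YAML mapping")
  for (k in names(overrides))
    if (!is.null(overrides[[k]])) cfg[[k]] <- overrides[[k]]
  unknown <- setdiff(names(cfg), .config_keys)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  defaults <- list(n_total = 2000, n_replicates = 10, y_tolerance = 0.02,
                   epsilons = c(0.05, 0.06, 0.07),
                   xs = c(0.01, 0.02, 0.05, 0.1, 0.2, 0.4),
                   ys = seq(0.1, 0.95, length.out = 6),
                   y_range = c(0.05, 0.99), seed = 1L, out_dir = ".")
  for (k in names(defaults))
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  aliases <- cfg$column_aliases
  if (!is.null(aliases)) cfg$column_aliases <- unlist(aliases)
  # model_params() performs the parameter validation
  pkeys <- intersect(names(cfg),
                     names(formals(model_params)))
  cfg_params <- do.call(model_params, cfg[pkeys])
  structure(list(params = cfg_params,
                 n_total = cfg$n_total, n_replicates = cfg$n_replicates,
                 xs = cfg$xs, ys = cfg$ys, y_tolerance = cfg$y_tolerance,
                 epsilons = cfg$epsilons, y_range = cfg$y_range,
                 seed = as.integer(cfg$seed), out_dir = cfg$out_dir,
                 column_aliases = cfg$column_aliases),
            class = "run_config")
}
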