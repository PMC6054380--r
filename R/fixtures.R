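#' Toy world configuration
#'
#' A tiny deterministic world (12 x 12 patches, 3 firms, 12 households, 2
#' speculators) used by the test suite for conservation audits and by the
#' command-line \code{fixtures} subcommand. Dynamics are the standard
#' defaults at miniature scale; a seed plus this configuration fully
#' determines a run.
#'
#' @param ... overrides as named \code{"section.key"} values.
#' @return an \code{ecodebt_config}.
#' @export
#' @examples
#' run <- run_simulation(toy_config(), seed = 42, horizon = 10)
toy_config <- function(...) {
  cfg <- default_config(grid_rows = 12L, grid_cols = 12L)
  cfg$economy$n_firms <- 3L
  cfg$economy$n_households <- 12L
  cfg$economy$n_speculators <- 2L
  cfg$simulation$horizon <- 100L
  overrides <- list(...)
  for (key in names(overrides)) cfg <- config_set(cfg, key, overrides[[key]])
  validate_config(cfg)
  cfg
}

#' Emit fixture configurations to disk
#'
#' Writes the toy-world configuration and the four scenario presets as
#' YAML files into a directory, for use from the command line.
#'
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_fixtures <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_config(toy_config(), file.path(dir, "toy.yaml"))
  for (p in c("fractional_no_gov", "fractional_gov25",
              "fractional_gov50", "full_reserve")) {
    write_config(scenario_preset(p), file.path(dir, paste0(p, ".yaml")))
  }
  invisible(dir)
}
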