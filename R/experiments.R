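#' Classify a run into a dynamic regime
#'
#' A run is a \code{collapse} when it halted on resource collapse;
#' \code{stable} when the final resource stock holds at least
#' \code{stability_fraction} of the initial stock and the stock trend over
#' the last quartile of the series is non-negative; \code{decline}
#' otherwise.
#'
#' @param indicators the indicator data frame of a run (non-empty).
#' @param halt the run's halt metadata (list with \code{reason}).
#' @param stability_fraction stock fraction required for stability.
#' @param initial_stock initial total stock; defaults to the first recorded
#'   stock value.
#' @return one of \code{"collapse"}, \code{"stable"}, \code{"decline"}.
#' @export
classify_run <- function(indicators, halt, stability_fraction = 0.25,
                         initial_stock = NULL) {
  if (is.null(indicators) || nrow(indicators) == 0) {
    stop("cannot classify an empty indicator series", call. = FALSE)
  }
  if (identical(halt$reason, "resource_collapse")) return("collapse")
  stock <- indicators$natural_resource_stock
  init <- initial_stock %||% stock[1]
  n <- length(stock)
  tail_idx <- seq(max(1L, n - floor(n / 4) + 1L), n)
  slope <- if (length(tail_idx) > 1) {
    stats::coef(stats::lm.fit(cbind(1, seq_along(tail_idx)),
                              stock[tail_idx]))[2]
  } else 0
  flat_tol <- 1e-8 * max(abs(stock), 1) # numerically flat counts as flat
  if (stock[n] >= stability_fraction * init && slope >= -flat_tol) {
    "stable"
  } else {
    "decline"
  }
}

#' Run a replicate ensemble of one scenario
#'
#' Runs \code{replicates} seeded copies of a scenario (seeds
#' \code{base_seed} to \code{base_seed + replicates - 1}) and summarizes
#' every indicator per tick with the mean and standard error (sample
#' standard deviation over \eqn{\sqrt{n}}) across the runs still alive at
#' that tick. Runs that collapse early simply stop contributing; the
#' per-tick survivor counts are reported alongside.
#'
#' @param config an \code{ecodebt_config}, or a preset name accepted by
#'   [scenario_preset()].
#' @param replicates number of replicate runs (at least 1; at least 2 for
#'   error bands).
#' @param base_seed first seed.
#' @param horizon optional horizon override.
#' @param grid_rows,grid_cols grid size used when \code{config} is a
#'   preset name.
#' @return an object of class \code{ecodebt_ensemble}: per-tick
#'   \code{mean} and \code{se} matrices (tick by indicator; the error band
#'   is \code{NA} with a single replicate), \code{survivors},
#'   \code{regimes}, \code{collapse_ticks} (\code{NA} for runs that never
#'   collapse), per-run \code{totals}, and the stored \code{runs}.
#' @export
run_ensemble <- function(config, replicates = 20L, base_seed = 1L,
                         horizon = NULL, grid_rows = 100L,
                         grid_cols = 100L) {
  stopifnot(replicates >= 1)
  if (is.character(config)) {
    config <- scenario_preset(config, grid_rows = grid_rows,
                              grid_cols = grid_cols)
  }
  seeds <- base_seed + seq_len(replicates) - 1L
  runs <- lapply(seeds, function(s) {
    run_simulation(config, seed = s, horizon = horizon)
  })
  summarize_ensemble(runs, seeds)
}

# Collate stored runs into per-tick mean/SE summaries. Kept separate so
# the collation can be checked against a brute-force recomputation.
summarize_ensemble <- function(runs, seeds = seq_along(runs)) {
  vars <- setdiff(.indicator_names, "tick")
  max_t <- max(vapply(runs, function(r) nrow(r$indicators), 1L))
  n_runs <- length(runs)
  mean_mat <- matrix(NA_real_, nrow = max_t, ncol = length(vars),
                     dimnames = list(NULL, vars))
  se_mat <- mean_mat
  survivors <- integer(max_t)
  for (t in seq_len(max_t)) {
    alive <- which(vapply(runs, function(r) nrow(r$indicators) >= t,
                          logical(1)))
    survivors[t] <- length(alive)
    if (!length(alive)) next
    for (v in vars) {
      vals <- vapply(alive, function(i) runs[[i]]$indicators[[v]][t],
                     numeric(1))
      mean_mat[t, v] <- mean(vals)
      se_mat[t, v] <- if (length(vals) > 1) {
        stats::sd(vals) / sqrt(length(vals))
      } else NA_real_
    }
  }
  regimes <- vapply(runs, function(r) {
    classify_run(r$indicators, r$halt,
                 initial_stock = r$totals$initial_stock)
  }, character(1))
  collapse_ticks <- vapply(runs, function(r) {
    if (r$halt$reason == "resource_collapse") r$halt$tick else NA_integer_
  }, integer(1))
  totals <- do.call(rbind, lapply(runs, function(r) {
    data.frame(credit_issued = r$totals$credit_issued,
               bad_debt = r$totals$bad_debt,
               final_stock = r$totals$final_stock)
  }))
  totals$seed <- seeds
  totals$regime <- regimes
  out <- list(mean = mean_mat, se = se_mat, survivors = survivors,
              regimes = regimes, collapse_ticks = collapse_ticks,
              totals = totals, seeds = seeds, runs = runs)
  class(out) <- c("ecodebt_ensemble", "list")
  out
}

#' @export
print.ecodebt_ensemble <- function(x, ...) {
  n <- length(x$runs)
  cat("<ecodebt_ensemble>", n, "replicates\n")
  cat("  regimes:", paste(sprintf("%s=%d", names(table(x$regimes)),
                                  table(x$regimes)), collapse = " "), "\n")
  cat(sprintf("  collapse frequency: %.2f; mean credit issued: %.1f\n",
              mean(!is.na(x$collapse_ticks)),
              mean(x$totals$credit_issued)))
  invisible(x)
}

#' One-factor-at-a-time sensitivity sweep
#'
#' Re-runs an ensemble for each value of a single configuration parameter
#' (addressed as \code{"section.key"}), all other parameters held at the
#' base configuration. Unknown parameter names are an error.
#'
#' @param config base \code{ecodebt_config} (or preset name).
#' @param parameter dotted parameter name, e.g.
#'   \code{"governance.critical_biomass_fraction"}.
#' @param values vector of values to sweep.
#' @param replicates,base_seed,horizon,grid_rows,grid_cols passed to
#'   [run_ensemble()]; the same seeds are reused for every value so the
#'   comparison is paired.
#' @return an object of class \code{ecodebt_sweep}: the per-value
#'   \code{summaries} (named list of ensembles) and a \code{table} with
#'   one row per value (collapse frequency, mean collapse tick, mean final
#'   stock, mean credit issued).
#' @export
ofat_sweep <- function(config, parameter, values, replicates = 20L,
                       base_seed = 1L, horizon = NULL, grid_rows = 100L,
                       grid_cols = 100L) {
  if (is.character(config)) {
    config <- scenario_preset(config, grid_rows = grid_rows,
                              grid_cols = grid_cols)
  }
  config_get(config, parameter) # errors on unknown parameter
  summaries <- lapply(values, function(v) {
    run_ensemble(config_set(config, parameter, v),
                 replicates = replicates, base_seed = base_seed,
                 horizon = horizon)
  })
  names(summaries) <- as.character(values)
  tab <- do.call(rbind, lapply(seq_along(values), function(i) {
    s <- summaries[[i]]
    data.frame(
      parameter = parameter,
      value = values[i],
      collapse_frequency = mean(!is.na(s$collapse_ticks)),
      mean_collapse_tick = mean(s$collapse_ticks, na.rm = TRUE),
      mean_final_stock = mean(s$totals$final_stock),
      mean_credit_issued = mean(s$totals$credit_issued)
    )
  }))
  out <- list(summaries = summaries, table = tab)
  class(out) <- c("ecodebt_sweep", "list")
  out
}

#' @export
print.ecodebt_sweep <- function(x, ...) {
  cat("<ecodebt_sweep>\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Write ensemble summaries to CSV
#'
#' @param ens an \code{ecodebt_ensemble}.
#' @param summary_csv per-tick mean/SE/survivors table path.
#' @param regimes_csv optional per-run regime/totals table path.
#' @return \code{summary_csv}, invisibly.
#' @export
write_ensemble <- function(ens, summary_csv, regimes_csv = NULL) {
  vars <- colnames(ens$mean)
  long <- data.frame(tick = seq_len(nrow(ens$mean)),
                     survivors = ens$survivors)
  for (v in vars) {
    long[[paste0(v, "_mean")]] <- ens$mean[, v]
    long[[paste0(v, "_se")]] <- ens$se[, v]
  }
  utils::write.csv(long, summary_csv, row.names = FALSE)
  if (!is.null(regimes_csv)) {
    utils::write.csv(ens$totals, regimes_csv, row.names = FALSE)
  }
  invisible(summary_csv)
}
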