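#' Default simulation configuration
#'
#' Builds the full nested configuration for a simulation run, with four
#' sections: \code{environment}, \code{economy}, \code{governance} and
#' \code{simulation}. Agent counts default to fixed densities per patch so
#' that economic pressure on the landscape is approximately invariant to
#' grid size. All coefficients are documented placeholders chosen to emulate
#' the study conditions (the original parameter table is not reproduced
#' here); see the methods vignette for the rationale behind each default.
#'
#' @param grid_rows,grid_cols landscape dimensions in patches.
#' @return a nested list of class \code{ecodebt_config}.
#' @export
#' @examples
#' cfg <- default_config(grid_rows = 10, grid_cols = 10)
#' cfg$economy$cash_reserve_ratio
default_config <- function(grid_rows = 100L, grid_cols = 100L) {
  n_patches <- as.integer(grid_rows) * as.integer(grid_cols)
  cfg <- list(
    environment = list(
      grid_rows = as.integer(grid_rows),
      grid_cols = as.integer(grid_cols),
      regrowth_rate = 0.08,          # logistic r, per tick
      carrying_capacity = 100,       # K, biomass units per patch
      initial_stock_per_patch = 100, # pristine landscape at capacity
      yield_factor = 1.26,           # F_y, forest-land placeholder
      equivalence_factor = 1.28,     # F_eq, forest-land placeholder
      restoration_rate = 0.5,        # biomass per tick on restoring patches
      reactivation_fraction = 0.25   # restoring patch rejoins at this K fraction
    ),
    economy = list(
      n_firms = max(2L, as.integer(round(0.005 * n_patches))),
      n_households = max(8L, as.integer(round(0.08 * n_patches))),
      n_speculators = max(2L, as.integer(round(0.002 * n_patches))),
      cash_reserve_ratio = 0.02,     # fraction of deposits withdrawable
      conversion_factor = 0.35,      # c: goods per biomass x labour unit
      accelerator = 1.5,             # v in the demand rule
      choice_sharpness = 2,          # household firm-choice concentration
      demand_smoothing = 0.5,        # adaptive demand expectation weight
      max_workers_per_firm = 4L,     # workforce concentration cap
      correction_factor = 2e-4,      # M_c in the investment rule
      wage_coefficient = 0.3,        # W_c: payroll share of firm capital
      credit_interest_rate = 0.03,   # per tick
      deposit_interest_rate = 0.005, # per tick
      loan_term = 10L,               # ticks, equal-principal amortization
      tech_investment_fraction = 0.5,
      tech_efficiency_gain = 0.03,   # efficiency added per money unit spent
      distance_decay = 0.3,           # exp decay per grid step in demand
      init_firm_capital = 100,
      init_household_capital = 20,
      init_speculator_capital = 100,
      init_bank_equity = 50,
      bankruptcy_floor = 1,          # capital below this forces default
      default_patience = 8L,         # distressed ticks before liquidation
      debt_to_capital_cap = 5,       # creditworthiness rule
      credit_assessment_floor = 20,  # capital floor in the lending rule
      borrow_appetite = 0.4,         # fraction of capital requested per tick
      min_loan = 1,
      spec_borrow_fraction = 0.5,    # speculator stake as fraction of capital
      expansion_cost = 200,          # endowment of a new branch firm
      expansion_skin_fraction = 0.5, # own capital required before expanding
      max_firm_factor = 6,           # firm population cap, x initial count
      reserve_floor = 1,             # guards the price rule denominator
      speculation_price_floor = 1,   # guards the price rule numerator
      price_adjust = 0.15,           # partial price adjustment per tick
      price_min = 1e-3,
      growth_clamp = 0.2,            # |k_g| bound per tick, numerical guard
      energy_use = 1,                # household energy drawn per tick
      energy_target = 5,             # desired energy buffer (goods units)
      hire_threshold = 50,           # min firm capital to recruit workers
      capital_per_worker = 20,       # workforce capacity per unit capital
      extraction_unit_cost = 0.5,    # money per biomass unit extracted
      reserve_decay = 0.08,          # biomass reserve spoilage per tick
      relocate_when_depleted = TRUE,
      restoration_cost = 10          # paid by the last harvester per patch
    ),
    governance = list(
      critical_biomass_fraction = 0, # 0 never triggers (no intervention)
      restoration_capacity = 3L,     # patches enrolled per tick, at most
      tech_investment_cap = 0,
      speculation_cap = 0,
      protection_increment = 0.03,   # protected-area expansion at activation
      restoration_mandate = TRUE
    ),
    simulation = list(
      horizon = 250L,
      collapse_epsilon = 0.01,       # collapse when stock < 1% of initial
      audit = TRUE
    )
  )
  class(cfg) <- c("ecodebt_config", "list")
  cfg
}

#' Scenario presets
#'
#' The four study scenarios: a fractional-reserve banking system (cash
#' reserve ratio 0.02) without intervention and with conservation policies
#' triggered at 25\% or 50\% of the initial resource stock, and a
#' full-reserve system (ratio 1) without intervention.
#'
#' @param name preset name.
#' @param grid_rows,grid_cols landscape dimensions (agent counts scale with
#'   area).
#' @param ... overrides as named \code{"section.key"} values, e.g.
#'   \code{`simulation.horizon` = 100}.
#' @return an \code{ecodebt_config}.
#' @export
#' @examples
#' cfg <- scenario_preset("fractional_gov50", grid_rows = 20, grid_cols = 20)
#' cfg$governance$critical_biomass_fraction
scenario_preset <- function(name = c("fractional_no_gov", "fractional_gov25",
                                     "fractional_gov50", "full_reserve"),
                            grid_rows = 100L, grid_cols = 100L, ...) {
  name <- match.arg(name)
  cfg <- default_config(grid_rows = grid_rows, grid_cols = grid_cols)
  cfg$economy$cash_reserve_ratio <- if (name == "full_reserve") 1.0 else 0.02
  cfg$governance$critical_biomass_fraction <- switch(name,
    fractional_no_gov = 0,
    fractional_gov25 = 0.25,
    fractional_gov50 = 0.5,
    full_reserve = 0 # no intervention under full reserve
  )
  overrides <- list(...)
  for (key in names(overrides)) cfg <- config_set(cfg, key, overrides[[key]])
  attr(cfg, "preset") <- name
  validate_config(cfg)
  cfg
}

#' Get or set a configuration value by dotted path
#'
#' @param cfg an \code{ecodebt_config}.
#' @param key a \code{"section.key"} string, e.g.
#'   \code{"economy.credit_interest_rate"}.
#' @param value replacement value (for \code{config_set}).
#' @return the value, or the modified configuration.
#' @export
config_get <- function(cfg, key) {
  path <- strsplit(key, ".", fixed = TRUE)[[1]]
  if (length(path) != 2L || is.null(cfg[[path[1]]]) ||
      !path[2] %in% names(cfg[[path[1]]])) {
    stop("unknown configuration parameter: ", key, call. = FALSE)
  }
  cfg[[path[1]]][[path[2]]]
}

#' @rdname config_get
#' @export
config_set <- function(cfg, key, value) {
  path <- strsplit(key, ".", fixed = TRUE)[[1]]
  if (length(path) != 2L || is.null(cfg[[path[1]]]) ||
      !path[2] %in% names(cfg[[path[1]]])) {
    stop("unknown configuration parameter: ", key, call. = FALSE)
  }
  cfg[[path[1]]][[path[2]]] <- value
  cfg
}

.check_num <- function(x, field, min = -Inf, max = Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop("configuration field '", field, "' must be a single number",
         call. = FALSE)
  }
  bad_lo <- if (strict_min) x <= min else x < min
  if (bad_lo || x > max) {
    stop("configuration field '", field, "' out of range [",
         if (strict_min) paste0("(", min) else min, ", ", max, "]: ", x,
         call. = FALSE)
  }
  invisible(x)
}

#' Validate a configuration
#'
#' Checks types and ranges for every field; errors name the offending field.
#'
#' @param cfg an \code{ecodebt_config}.
#' @return the configuration, invisibly, if valid.
#' @export
validate_config <- function(cfg) {
  for (sec in c("environment", "economy", "governance", "simulation")) {
    if (is.null(cfg[[sec]])) {
      stop("configuration is missing the '", sec, "' section", call. = FALSE)
    }
  }
  env <- cfg$environment
  .check_num(env$grid_rows, "environment.grid_rows", min = 1)
  .check_num(env$grid_cols, "environment.grid_cols", min = 1)
  .check_num(env$regrowth_rate, "environment.regrowth_rate", min = 0)
  .check_num(env$carrying_capacity, "environment.carrying_capacity",
             min = 0, strict_min = TRUE)
  .check_num(env$initial_stock_per_patch,
             "environment.initial_stock_per_patch", min = 0,
             max = env$carrying_capacity)
  .check_num(env$yield_factor, "environment.yield_factor",
             min = 0, strict_min = TRUE)
  .check_num(env$equivalence_factor, "environment.equivalence_factor",
             min = 0, strict_min = TRUE)
  .check_num(env$restoration_rate, "environment.restoration_rate", min = 0)
  .check_num(env$reactivation_fraction, "environment.reactivation_fraction",
             min = 0, max = 1)
  eco <- cfg$economy
  .check_num(eco$n_firms, "economy.n_firms", min = 0)
  .check_num(eco$n_households, "economy.n_households", min = 0)
  .check_num(eco$n_speculators, "economy.n_speculators", min = 0)
  .check_num(eco$cash_reserve_ratio, "economy.cash_reserve_ratio",
             min = 0, max = 1, strict_min = TRUE)
  .check_num(eco$conversion_factor, "economy.conversion_factor",
             min = 0, strict_min = TRUE)
  .check_num(eco$accelerator, "economy.accelerator",
             min = 0, strict_min = TRUE)
  .check_num(eco$correction_factor, "economy.correction_factor", min = 0)
  .check_num(eco$wage_coefficient, "economy.wage_coefficient",
             min = 0, max = 1)
  .check_num(eco$credit_interest_rate, "economy.credit_interest_rate",
             min = 0)
  .check_num(eco$deposit_interest_rate, "economy.deposit_interest_rate",
             min = 0, max = eco$credit_interest_rate)
  .check_num(eco$loan_term, "economy.loan_term", min = 1)
  .check_num(eco$tech_investment_fraction,
             "economy.tech_investment_fraction", min = 0, max = 1)
  .check_num(eco$tech_efficiency_gain, "economy.tech_efficiency_gain",
             min = 0)
  .check_num(eco$distance_decay, "economy.distance_decay", min = 0)
  .check_num(eco$debt_to_capital_cap, "economy.debt_to_capital_cap", min = 0)
  gov <- cfg$governance
  .check_num(gov$critical_biomass_fraction,
             "governance.critical_biomass_fraction", min = 0, max = 1)
  .check_num(gov$tech_investment_cap, "governance.tech_investment_cap",
             min = 0, max = 1)
  .check_num(gov$speculation_cap, "governance.speculation_cap", min = 0)
  .check_num(gov$protection_increment, "governance.protection_increment",
             min = 0, max = 1)
  sim <- cfg$simulation
  .check_num(sim$horizon, "simulation.horizon", min = 0)
  .check_num(sim$collapse_epsilon, "simulation.collapse_epsilon",
             min = 0, max = 1)
  invisible(cfg)
}

#' Read or write a configuration file
#'
#' Configurations are stored as YAML with the four standard sections
#' (\code{environment}, \code{economy}, \code{governance},
#' \code{simulation}); keys absent from the file keep their defaults.
#'
#' @param path file path.
#' @param cfg an \code{ecodebt_config}.
#' @return \code{read_config}: a validated \code{ecodebt_config}.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  dims <- list(
    grid_rows = raw$environment$grid_rows %||% 100L,
    grid_cols = raw$environment$grid_cols %||% 100L
  )
  cfg <- default_config(grid_rows = dims$grid_rows,
                        grid_cols = dims$grid_cols)
  for (sec in intersect(names(raw), names(cfg))) {
    for (key in names(raw[[sec]])) {
      if (!key %in% names(cfg[[sec]])) {
        stop("unknown configuration parameter: ", sec, ".", key,
             call. = FALSE)
      }
      cfg[[sec]][[key]] <- raw[[sec]][[key]]
    }
  }
  validate_config(cfg)
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  plain <- unclass(cfg)
  attr(plain, "preset") <- NULL
  yaml::write_yaml(plain, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
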