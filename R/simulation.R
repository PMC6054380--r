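#' Initialize a simulation state
#'
#' Builds the full world state from a configuration and a seed: the patch
#' landscape, the firm/household/speculator populations, the bank balance
#' sheet, the government, and the market aggregates. All randomness in the
#' run (placement, activation order, protected-area siting) flows from this
#' single seed, so identical \code{(config, seed)} pairs yield identical
#' runs.
#'
#' @param config an \code{ecodebt_config}.
#' @param seed integer RNG seed.
#' @return an object of class \code{ecodebt_state}.
#' @export
new_simulation <- function(config, seed = 1L) {
  validate_config(config)
  set.seed(as.integer(seed))
  patches <- make_patches(config$environment)
  firms <- make_firms(config, patches)
  households <- make_households(config, firms, patches)
  firms$labour <- tabulate(match(households$employer, firms$firm_id),
                           nbins = nrow(firms))
  state <- list(
    tick = 0L,
    config = config,
    seed = as.integer(seed),
    patches = patches,
    firms = firms,
    households = households,
    speculators = make_speculators(config),
    bank = make_bank(config$economy),
    loans = empty_loans(),
    next_loan_id = 1L,
    government = make_government(config$governance),
    market = list(Pk = 0, gdp = 0, gdp_prev = 0, kg = 0, Y = 0,
                  agd_prev = 0, mean_price = 1, mean_price_prev = 1,
                  price_rising = FALSE, gdp_rising = FALSE,
                  real_gdp_prev = 0),
    debt_prev = 0,
    initial_stock = total_resource_stock(patches),
    max_firms = config$economy$max_firm_factor *
      max(nrow(firms), 1L),
    halted = FALSE,
    halt_reason = "none",
    indicators = list(),
    audit = list(),
    process_order = character(0)
  )
  class(state) <- c("ecodebt_state", "list")
  state
}

.indicator_names <- c(
  "tick", "natural_resource_stock", "real_gdp_growth",
  "debt_growth_rate", "speculation_rate", "monetary_capital_firms",
  "monetary_capital_households", "monetary_capital_bank",
  "technology_efficiency", "mean_price", "employment",
  "active_speculators"
)

# Total money across all sectors; loans create it, principal repayment and
# write-offs destroy it, everything else is a transfer.
.money_total <- function(state) {
  sum(state$firms$capital) + sum(state$households$capital) +
    sum(state$speculators$capital) + state$bank$equity
}

#' Advance the simulation by one tick
#'
#' Executes the per-tick processes in their fixed order: (i) patches
#' regrow/restore biomass; (ii) firms extract resources; (iii) households
#' compute demand, movement and energy; (iv) firms set prices and sell;
#' (v) firms compute labour and finance (productivity, wages, technology
#' investment, hiring); (vi) the bank computes its accounts; (vii) firms
#' borrow credit; (viii) firms consider business expansion; (ix)
#' speculators bet; (x) firms and speculators repay credit; (xi) the
#' government checks and applies conservation policies. An indicator row
#' and a conservation-audit row are then recorded and collapse detection
#' runs. The executed process order is kept in \code{state$process_order}.
#'
#' @param state an \code{ecodebt_state} that is not halted.
#' @return the updated state.
#' @export
step_simulation <- function(state) {
  if (state$halted) {
    stop("cannot step a halted simulation", call. = FALSE)
  }
  cfg <- state$config
  env <- cfg$environment
  eco <- cfg$economy
  market <- state$market
  bank <- state$bank
  loans <- state$loans
  gov <- state$government
  order_log <- character(0)
  flows <- list(granted = 0, repaid = 0, written_off = 0)

  ## (i) patches compute biomass stock
  es <- environment_step(state$patches, env)
  patches <- es$patches
  order_log <- c(order_log, "patches_biomass")

  ## (ii) firms extract resources
  firms <- state$firms
  households <- state$households
  extracted_total <- 0
  spoiled_total <- 0
  if (nrow(firms)) {
    # harvested biomass held in reserve spoils before this tick's harvest
    spoiled_total <- sum(firms$reserve) * eco$reserve_decay
    firms$reserve <- firms$reserve * (1 - eco$reserve_decay)
    ex <- extract_resources(firms, patches, eco, market$agd_prev)
    firms <- ex$firms
    patches <- ex$patches
    extracted_total <- sum(ex$extracted)
    if (ex$investment > 0 && nrow(households)) {
      households$capital <- households$capital +
        ex$investment / nrow(households)
    }
  }
  order_log <- c(order_log, "firms_extract")

  ## (iii) households compute demand, movement and energy
  agd <- 0
  chosen <- integer(0)
  hh_demand <- numeric(0)
  sellers <- which(!firms$bankrupt)
  if (nrow(households) && length(sellers)) {
    frow <- patches$row[firms$patch[sellers]]
    fcol <- patches$col[firms$patch[sellers]]
    dmat <- abs(outer(households$row, frow, "-")) +
      abs(outer(households$col, fcol, "-"))
    score <- sweep(exp(eco$distance_decay * dmat), 2, firms$price[sellers],
                   "*")
    # probabilistic discrete choice: cheap nearby firms attract most of
    # the custom without ever monopolizing it
    w <- score^(-eco$choice_sharpness)
    w <- w / rowSums(w)
    u <- stats::runif(nrow(w))
    pick <- if (ncol(w) == 1L) {
      rep(1L, nrow(w))
    } else {
      max.col(t(apply(w, 1, cumsum)) >= u, ties.method = "first")
    }
    chosen <- sellers[pick]
    trow <- frow[pick]
    tcol <- fcol[pick]
    households$row <- households$row + sign(trow - households$row)
    households$col <- households$col + sign(tcol - households$col)
    d <- abs(trow - households$row) + abs(tcol - households$col)
    base <- demand_goods(households$capital, firms$price[chosen],
                         eco$accelerator,
                         d, eco$distance_decay)
    hh_demand <- base
    households$demand <- hh_demand
    agd <- sum(hh_demand)
  }
  households$energy <- pmax(0, households$energy - eco$energy_use)
  order_log <- c(order_log, "households_demand")

  ## (iv) firms compute prices and sales
  gdp <- 0
  output <- 0
  if (nrow(firms)) {
    d_firm <- numeric(nrow(firms))
    if (length(chosen)) {
      agg <- tapply(hh_demand, chosen, sum)
      d_firm[as.integer(names(agg))] <- as.numeric(agg)
    }
    raw <- set_price(d_firm[sellers], market$Pk, firms$reserve[sellers],
                     eco)
    firms$price[sellers] <- pmax(
      (1 - eco$price_adjust) * firms$price[sellers] +
        eco$price_adjust * raw,
      eco$price_min
    )
    if (length(chosen)) {
      for (f in unique(chosen)) {
        buyers <- which(chosen == f)
        sale <- sell_goods(
          hh_demand[buyers], firms$reserve[f], firms$price[f],
          eco$conversion_factor,
          spendable = households$capital[buyers]
        )
        households$capital[buyers] <- households$capital[buyers] -
          sale$spend
        households$energy[buyers] <- households$energy[buyers] +
          sale$goods
        firms$capital[f] <- firms$capital[f] + sale$revenue
        firms$reserve[f] <- max(0, firms$reserve[f] - sale$biomass_used)
        gdp <- gdp + sale$revenue
        output <- output + sum(sale$goods)
      }
    }
    firms$demand_prev <- (1 - eco$demand_smoothing) * firms$demand_prev +
      eco$demand_smoothing * d_firm
  }
  market$gdp_rising <- gdp > market$gdp_prev
  market$gdp_prev <- market$gdp
  market$gdp <- gdp
  market$Y <- output
  mp <- if (length(sellers)) mean(firms$price[sellers]) else
    market$mean_price
  market$mean_price_prev <- market$mean_price
  market$mean_price <- mp
  market$price_rising <- mp > market$mean_price_prev
  real_gdp_now <- if (mp > 0) gdp / mp else 0
  kg_raw <- if (market$real_gdp_prev > 0) {
    (real_gdp_now - market$real_gdp_prev) / market$real_gdp_prev
  } else 0
  market$kg <- max(-eco$growth_clamp, min(eco$growth_clamp, kg_raw))
  order_log <- c(order_log, "firms_prices_sales")

  ## (v) firms compute labour and finance
  if (nrow(firms)) {
    firms$productivity <- compute_productivity(
      firms$capital, firms$capital_prev, firms$labour
    )
    w <- pay_wages(firms$capital, firms$labour, eco)
    firms$wage <- w$wage
    if (sum(w$payroll) > 0) {
      firms$capital <- firms$capital - w$payroll
      emp <- match(households$employer, firms$firm_id)
      paid <- ifelse(is.na(emp), 0, w$wage[emp])
      households$capital <- households$capital + paid
    }
    # only liquidated firms release their workers; wages already scale
    # with capital, so mere illiquidity does not destroy the workforce
    broke <- firms$firm_id[firms$bankrupt]
    households$employer[households$employer %in% broke] <- NA_integer_
    # technology investment (capped under intervention)
    cap <- if (gov$intervention_active) gov$tech_investment_cap else NULL
    ti <- invest_in_technology(firms, eco, cap)
    firms <- ti$firms
    if (ti$spend > 0 && nrow(households)) {
      households$capital <- households$capital +
        ti$spend / nrow(households)
    }
    # hiring: richest solvent firms recruit the unemployed first
    jobless <- which(is.na(households$employer))
    if (length(jobless)) {
      firms$labour <- tabulate(match(households$employer,
                                     firms$firm_id),
                               nbins = nrow(firms))
      hirers <- which(!firms$bankrupt &
                        firms$capital >= eco$hire_threshold)
      if (length(hirers)) {
        hirers <- hirers[order(-firms$capital[hirers])]
        slots <- pmax(0, pmin(floor(firms$capital[hirers] /
                                      eco$capital_per_worker),
                              eco$max_workers_per_firm) -
                        firms$labour[hirers])
        offer <- rep(firms$firm_id[hirers], slots)
        take <- min(length(jobless), length(offer))
        if (take > 0) {
          households$employer[jobless[seq_len(take)]] <-
            offer[seq_len(take)]
        }
      }
    }
    firms$labour <- tabulate(match(households$employer, firms$firm_id),
                             nbins = nrow(firms))
  }
  order_log <- c(order_log, "firms_labour_finance")

  ## (vi) bank computes finance
  ba <- bank_accounting(bank, households$capital, sum(loans$balance), eco)
  bank <- ba$bank
  if (nrow(households)) {
    households$capital <- households$capital + ba$interest_paid
  }
  order_log <- c(order_log, "bank_finance")

  ## (vii) firms borrow credits
  if (nrow(firms)) {
    firms$debt <- .debt_of(loans, "firm", firms$firm_id)
    borrowers <- which(!firms$bankrupt)
    if (length(borrowers) > 1) borrowers <- sample(borrowers)
    new_amt <- numeric(0)
    new_who <- integer(0)
    cap_v <- firms$capital
    debt_v <- firms$debt
    reserves_v <- bank$reserves
    for (i in borrowers) {
      # growth appetite, or a working-capital line when underfunded
      want <- max(eco$borrow_appetite * cap_v[i],
                  eco$hire_threshold - cap_v[i])
      if (want < eco$min_loan || want > reserves_v) next
      worthy <- (debt_v[i] + want) /
        max(cap_v[i], eco$credit_assessment_floor) <=
        eco$debt_to_capital_cap
      if (!worthy) next
      reserves_v <- reserves_v - want
      cap_v[i] <- cap_v[i] + want
      debt_v[i] <- debt_v[i] + want
      new_amt <- c(new_amt, want)
      new_who <- c(new_who, firms$firm_id[i])
    }
    if (length(new_amt)) {
      bank$reserves <- reserves_v
      firms$capital <- cap_v
      firms$debt <- debt_v
      loans <- rbind(loans, data.frame(
        loan_id = NA_integer_, borrower_type = "firm",
        borrower = new_who, principal = new_amt, balance = new_amt,
        rate = eco$credit_interest_rate,
        ticks_remaining = as.integer(eco$loan_term)
      ))
      flows$granted <- flows$granted + sum(new_amt)
    }
  }
  order_log <- c(order_log, "firms_borrow")

  ## (viii) firms consider business expansion
  if (nrow(firms)) {
    exp_res <- consider_expansion(firms, patches, bank, loans, eco,
                                  max_firms = state$max_firms)
    firms <- exp_res$firms
    bank <- exp_res$bank
    loans <- exp_res$loans
    flows$granted <- flows$granted + exp_res$granted
  }
  order_log <- c(order_log, "firms_expand")

  ## (ix) speculators compute speculation
  specs <- state$speculators
  if (nrow(specs)) {
    sp <- speculator_step(specs, market, bank, loans, eco,
                          blocked = gov$intervention_active)
    specs <- sp$specs
    bank <- sp$bank
    loans <- sp$loans
    flows$granted <- flows$granted + sp$granted
  }
  market$Pk <- speculation_index(market$kg, market$Y)
  if (gov$intervention_active) {
    market$Pk <- min(market$Pk, gov$speculation_cap)
  }
  order_log <- c(order_log, "speculators")

  ## (x) firms and speculators compute credit repayment
  ## (vectorized over the whole ledger; borrowers do not interact within
  ## the tick, so this matches the per-borrower amortization exactly)
  if (nrow(loans)) {
    key <- paste0(loans$borrower_type, ".", loans$borrower)
    prin <- ifelse(loans$ticks_remaining > 0,
                   loans$balance / pmax(loans$ticks_remaining, 1),
                   loans$balance)
    intr <- loans$balance * loans$rate
    due_b <- rowsum(prin + intr, key)
    ukey <- rownames(due_b)
    utype <- sub("\\..*$", "", ukey)
    uid <- as.integer(sub("^[a-z]+\\.", "", ukey))
    jf <- match(uid, firms$firm_id)
    js <- match(uid, specs$spec_id)
    ufirm <- utype == "firm"
    cap_b <- ifelse(ufirm, firms$capital[jf], specs$capital[js])
    res_b <- ifelse(ufirm, firms$reserve[jf], 0)
    pay_b <- pmin(due_b[, 1], pmax(cap_b, 0))
    phi_b <- ifelse(due_b[, 1] > 0, pay_b / due_b[, 1], 0)
    phi_l <- phi_b[match(key, ukey)]
    interest_paid <- sum(phi_l * intr)
    flows$repaid <- flows$repaid + sum(phi_l * prin)
    loans$balance <- loans$balance - phi_l * prin
    loans$ticks_remaining <- pmax(loans$ticks_remaining - 1L, 0L)
    cap_after <- cap_b - pay_b
    bank$equity <- bank$equity + interest_paid
    distressed <- phi_b < 1 & cap_after < eco$bankruptcy_floor &
      res_b <= eco$reserve_floor
    liq_ok <- ifelse(ufirm, firms$distress[jf] >= eco$default_patience,
                     TRUE)
    defaulted <- distressed & liq_ok
    def_l <- defaulted[match(key, ukey)]
    expired <- !def_l & loans$ticks_remaining == 0L & loans$balance > 1e-9
    written <- sum(loans$balance[def_l | expired])
    loans$balance[def_l | expired] <- 0
    if (written > 0) {
      bank$bad_debt <- bank$bad_debt + written
      bank$equity <- bank$equity - written
      flows$written_off <- flows$written_off + written
    }
    loans <- loans[loans$balance > 1e-12, , drop = FALSE]
    # write back borrower capital and bankruptcy state
    fsel <- which(ufirm)
    if (length(fsel)) {
      firms$capital[jf[fsel]] <- cap_after[fsel]
      firms$distress[jf[fsel]] <- ifelse(distressed[fsel],
                                         firms$distress[jf[fsel]] + 1L, 0L)
      dead <- jf[fsel][defaulted[fsel]]
      if (length(dead)) {
        firms$bankrupt[dead] <- TRUE
        households$employer[households$employer %in%
                              firms$firm_id[dead]] <- NA_integer_
      }
    }
    ssel <- which(!ufirm)
    if (length(ssel)) {
      specs$capital[js[ssel]] <- cap_after[ssel]
      specs$active[js[ssel][defaulted[ssel]]] <- FALSE
    }
    if (nrow(firms)) firms$debt <- .debt_of(loans, "firm", firms$firm_id)
    firms$labour <- tabulate(match(households$employer, firms$firm_id),
                             nbins = nrow(firms))
  }
  order_log <- c(order_log, "credit_repayment")

  ## (xi) government computes conservation policies
  total_stock <- total_resource_stock(patches)
  if (!gov$intervention_active &&
      gov$critical_biomass_fraction > 0 &&
      check_trigger(total_stock, state$initial_stock, gov)) {
    gov$intervention_active <- TRUE
    # the speculation limit freezes the index at its prevailing level (or
    # the configured cap if that is higher): no further amplification, but
    # no engineered deflation shock either
    gov$speculation_cap <- max(gov$speculation_cap, market$Pk)
    ap <- apply_policies(patches, gov)
    patches <- ap$patches
    gov <- ap$gov
  }
  if (gov$intervention_active && gov$restoration_mandate) {
    rm_res <- restoration_mandate_step(patches, firms, households, eco,
                                       capacity = gov$restoration_capacity)
    patches <- rm_res$patches
    firms <- rm_res$firms
    households <- rm_res$households
  }
  order_log <- c(order_log, "government_policies")

  ## bookkeeping
  # refresh the deposit partition with end-of-tick balances (deposit
  # interest and restoration income land after the bank phase)
  bank$withdrawable <- bank$cash_reserve_ratio * sum(households$capital)
  if (nrow(loans) && anyNA(loans$loan_id)) {
    nas <- which(is.na(loans$loan_id))
    loans$loan_id[nas] <- seq(state$next_loan_id,
                              length.out = length(nas))
    state$next_loan_id <- state$next_loan_id + length(nas)
  }
  state$patches <- patches
  state$firms <- firms
  state$households <- households
  state$speculators <- specs
  state$bank <- bank
  state$loans <- loans
  state$government <- gov
  state$tick <- state$tick + 1L

  debt_total <- sum(loans$balance)
  real_gdp <- if (market$mean_price > 0) gdp / market$mean_price else 0
  act_firms <- !firms$bankrupt
  row <- c(
    tick = state$tick,
    natural_resource_stock = total_stock,
    real_gdp_growth = if (market$real_gdp_prev > 0) {
      (real_gdp - market$real_gdp_prev) / market$real_gdp_prev
    } else 0,
    debt_growth_rate = if (state$debt_prev > 0) {
      (debt_total - state$debt_prev) / state$debt_prev
    } else 0,
    speculation_rate = market$Pk,
    monetary_capital_firms = sum(firms$capital),
    monetary_capital_households = sum(households$capital),
    monetary_capital_bank = bank$equity,
    technology_efficiency = if (any(act_firms)) {
      mean(firms$tech_eff[act_firms])
    } else if (nrow(firms)) mean(firms$tech_eff) else 1,
    mean_price = market$mean_price,
    employment = sum(!is.na(households$employer)),
    active_speculators = sum(specs$active)
  )
  state$indicators[[state$tick]] <- row
  market$real_gdp_prev <- real_gdp
  state$debt_prev <- debt_total
  state$market <- market
  state$firms$capital_prev <- state$firms$capital
  state$audit[[state$tick]] <- c(
    tick = state$tick,
    loans_granted = flows$granted,
    principal_repaid = flows$repaid,
    principal_written_off = flows$written_off,
    money_total = .money_total(state),
    biomass_growth = es$growth,
    biomass_restoration = es$restoration,
    biomass_extracted = extracted_total,
    biomass_spoiled = spoiled_total,
    deposits = sum(households$capital),
    withdrawable = bank$withdrawable,
    credit_outstanding = debt_total
  )
  state$process_order <- order_log
  if (detect_collapse(state)) {
    state$halted <- TRUE
    state$halt_reason <- "resource_collapse"
  }
  state
}

.debt_of <- function(loans, type, ids) {
  out <- numeric(length(ids))
  sel <- loans$borrower_type == type
  if (any(sel)) {
    agg <- tapply(loans$balance[sel], loans$borrower[sel], sum)
    hit <- match(ids, as.integer(names(agg)))
    out[!is.na(hit)] <- as.numeric(agg)[hit[!is.na(hit)]]
  }
  out
}

#' Resource-collapse detection
#'
#' The system collapses when the total resource stock falls strictly below
#' \code{epsilon_fraction} of the initial stock; the run then halts with
#' reason \code{"resource_collapse"}.
#'
#' @param state an \code{ecodebt_state}.
#' @param epsilon_fraction collapse threshold as a fraction of the initial
#'   stock; defaults to the configured \code{simulation.collapse_epsilon}.
#' @return \code{TRUE} if the system has collapsed.
#' @export
detect_collapse <- function(state, epsilon_fraction = NULL) {
  eps <- epsilon_fraction %||% state$config$simulation$collapse_epsilon
  total_resource_stock(state$patches) < eps * state$initial_stock
}

#' Run a full simulation
#'
#' Initializes the world from a configuration and seed and steps it until
#' the horizon is reached or the resource base collapses. Identical
#' \code{(config, seed)} pairs produce identical output.
#'
#' @param config an \code{ecodebt_config} (see [default_config()] and
#'   [scenario_preset()]).
#' @param seed integer RNG seed.
#' @param horizon optional override of \code{config$simulation$horizon}.
#' @return an object of class \code{ecodebt_run}: a list with
#'   \code{indicators} (one row per completed tick), \code{audit}
#'   (per-tick conservation flows), \code{halt} (reason and tick),
#'   \code{totals} (cumulative credit issued, bad debt, final stock),
#'   \code{config} and \code{seed}.
#' @export
#' @examples
#' run <- run_simulation(toy_config(), seed = 1, horizon = 5)
#' head(run$indicators)
run_simulation <- function(config, seed = 1L, horizon = NULL) {
  if (!is.null(horizon)) config$simulation$horizon <- horizon
  state <- new_simulation(config, seed)
  h <- config$simulation$horizon
  credit <- 0
  while (state$tick < h && !state$halted) {
    state <- step_simulation(state)
  }
  ind <- if (length(state$indicators)) {
    as.data.frame(do.call(rbind, state$indicators))
  } else {
    as.data.frame(matrix(numeric(0), ncol = length(.indicator_names),
                         dimnames = list(NULL, .indicator_names)))
  }
  aud <- if (length(state$audit)) {
    as.data.frame(do.call(rbind, state$audit))
  } else NULL
  if (!is.null(aud)) credit <- sum(aud$loans_granted)
  reason <- if (state$halted) state$halt_reason else if (state$tick >= h) {
    "horizon_reached"
  } else "none"
  run <- list(
    indicators = ind,
    audit = aud,
    halt = list(reason = reason, tick = state$tick),
    totals = list(
      credit_issued = credit,
      bad_debt = state$bank$bad_debt,
      final_stock = total_resource_stock(state$patches),
      initial_stock = state$initial_stock
    ),
    config = config,
    seed = as.integer(seed),
    process_order = state$process_order,
    final_state = state
  )
  class(run) <- c("ecodebt_run", "list")
  run
}

#' @export
print.ecodebt_run <- function(x, ...) {
  cat("<ecodebt_run>\n")
  cat("  ticks:", nrow(x$indicators), " halt:", x$halt$reason,
      "at", x$halt$tick, "\n")
  cat(sprintf("  final stock: %.1f (%.1f%% of initial)\n",
              x$totals$final_stock,
              100 * x$totals$final_stock /
                max(x$totals$initial_stock, 1e-12)))
  cat(sprintf("  credit issued: %.1f  bad debt: %.1f\n",
              x$totals$credit_issued, x$totals$bad_debt))
  invisible(x)
}

#' @export
summary.ecodebt_run <- function(object, ...) {
  ind <- object$indicators
  out <- list(
    ticks = nrow(ind),
    halt = object$halt,
    regime = classify_run(ind, object$halt,
                          initial_stock = object$totals$initial_stock),
    totals = object$totals,
    peak_speculation = if (nrow(ind)) max(ind$speculation_rate) else NA,
    final_technology = if (nrow(ind)) {
      ind$technology_efficiency[nrow(ind)]
    } else NA
  )
  class(out) <- "summary.ecodebt_run"
  out
}

#' @export
print.summary.ecodebt_run <- function(x, ...) {
  cat("ecodebt run:", x$ticks, "ticks; halt:", x$halt$reason,
      "; regime:", x$regime, "\n")
  cat(sprintf("  credit issued %.1f, bad debt %.1f, final stock %.1f\n",
              x$totals$credit_issued, x$totals$bad_debt,
              x$totals$final_stock))
  invisible(x)
}

#' @export
plot.ecodebt_run <- function(x, indicators = c("natural_resource_stock",
                                               "speculation_rate",
                                               "debt_growth_rate",
                                               "technology_efficiency"),
                             ...) {
  ind <- x$indicators
  old <- graphics::par(mfrow = c(length(indicators), 1),
                       mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(old))
  for (v in indicators) {
    graphics::plot(ind$tick, ind[[v]], type = "l", xlab = "tick",
                   ylab = v, ...)
  }
  invisible(x)
}

#' Write run output
#'
#' Writes the indicator series as CSV (header exactly matching the
#' indicator field names), run metadata (seed, halt reason and tick) as a
#' JSON sidecar, and optionally the per-tick conservation audit as CSV.
#'
#' @param run an \code{ecodebt_run}.
#' @param csv path for the indicator CSV.
#' @param meta_json optional path for the JSON metadata sidecar.
#' @param audit_csv optional path for the audit CSV.
#' @return the indicator CSV path, invisibly.
#' @export
write_indicators <- function(run, csv, meta_json = NULL,
                             audit_csv = NULL) {
  utils::write.csv(run$indicators, csv, row.names = FALSE)
  if (!is.null(meta_json)) {
    jsonlite::write_json(
      list(seed = run$seed, halt_reason = run$halt$reason,
           halt_tick = run$halt$tick,
           horizon = run$config$simulation$horizon,
           credit_issued = run$totals$credit_issued,
           final_stock = run$totals$final_stock),
      meta_json, auto_unbox = TRUE, digits = NA
    )
  }
  if (!is.null(audit_csv) && !is.null(run$audit)) {
    utils::write.csv(run$audit, audit_csv, row.names = FALSE)
  }
  invisible(csv)
}
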