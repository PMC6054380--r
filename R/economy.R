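#' Agent constructors
#'
#' Build the initial firm, household and speculator populations and the
#' bank's balance sheet. Firms are placed on distinct random patches,
#' households at random grid cells; households are assigned to firms
#' round-robin as the initial workforce.
#'
#' @param cfg a full \code{ecodebt_config}.
#' @param patches the patch data frame.
#' @return data frames (or, for the bank, a list) describing the agents.
#' @name agent-constructors
NULL

#' @rdname agent-constructors
#' @export
make_firms <- function(cfg, patches) {
  eco <- cfg$economy
  n <- eco$n_firms
  open <- which(!patches$protected)
  sites <- if (length(open) >= n) sample(open, n) else
    sample(open, n, replace = TRUE)
  data.frame(
    firm_id = seq_len(n),
    patch = sites,
    capital = rep(as.numeric(eco$init_firm_capital), n),
    capital_prev = rep(as.numeric(eco$init_firm_capital), n),
    labour = rep(0L, n),
    reserve = rep(0, n),
    price = rep(1, n),
    productivity = rep(0, n),
    wage = rep(0, n),
    tech_eff = rep(1, n),
    demand_prev = rep(1, n), # small bootstrap demand for the first tick
    debt = rep(0, n),
    distress = rep(0L, n),
    bankrupt = rep(FALSE, n)
  )
}

#' @rdname agent-constructors
#' @export
make_households <- function(cfg, firms = NULL, patches = NULL) {
  eco <- cfg$economy
  env <- cfg$environment
  n <- eco$n_households
  hh <- data.frame(
    household_id = seq_len(n),
    row = sample.int(env$grid_rows, n, replace = TRUE) - 1L,
    col = sample.int(env$grid_cols, n, replace = TRUE) - 1L,
    capital = rep(as.numeric(eco$init_household_capital), n),
    employer = rep(NA_integer_, n),
    demand = rep(0, n),
    energy = rep(as.numeric(eco$energy_target), n)
  )
  if (eco$n_firms > 0) {
    jobs <- rep(seq_len(eco$n_firms), each = eco$max_workers_per_firm)
    hh$employer <- c(jobs, rep(NA_integer_, max(0, n - length(jobs))))[
      seq_len(n)]
    if (!is.null(firms) && !is.null(patches)) {
      # workers settle next to their employer, with a little scatter
      at <- match(hh$employer, firms$firm_id)
      at[is.na(at)] <- sample.int(nrow(firms), sum(is.na(at)),
                                  replace = TRUE)
      jit <- function(x, lim) pmin(pmax(x + sample(-2:2, n, TRUE), 0L),
                                   lim - 1L)
      hh$row <- jit(patches$row[firms$patch[at]], env$grid_rows)
      hh$col <- jit(patches$col[firms$patch[at]], env$grid_cols)
    }
  }
  hh
}

#' @rdname agent-constructors
#' @export
make_speculators <- function(cfg) {
  n <- cfg$economy$n_speculators
  data.frame(
    spec_id = seq_len(n),
    capital = rep(as.numeric(cfg$economy$init_speculator_capital), n),
    stake = rep(0, n),
    active = rep(TRUE, n)
  )
}

#' @rdname agent-constructors
#' @export
make_bank <- function(econ) {
  list(
    cash_reserve_ratio = econ$cash_reserve_ratio,
    withdrawable = 0,  # ratio-determined share of deposits, set each tick
    reserves = 0,      # lendable capacity, set each tick
    equity = as.numeric(econ$init_bank_equity), # interest surplus account
    bad_debt = 0
  )
}

# Empty loan ledger.
empty_loans <- function() {
  data.frame(
    loan_id = integer(0), borrower_type = character(0),
    borrower = integer(0), principal = numeric(0), balance = numeric(0),
    rate = numeric(0), ticks_remaining = integer(0)
  )
}

#' Household goods demand
#'
#' The demand rule evaluated with a configuration's accelerator and
#' distance-decay coefficients: \eqn{D = H_c/(P v) e^{-\lambda d}}, with
#' spending capped at the available capital.
#'
#' @param capital spendable household capital.
#' @param price the chosen firm's goods price.
#' @param econ the \code{economy} configuration section.
#' @param distance grid distance to the firm.
#' @return goods demanded.
#' @export
compute_demand <- function(capital, price, econ, distance = 0) {
  demand_goods(capital, price, econ$accelerator, distance,
               econ$distance_decay)
}

#' Firm resource extraction
#'
#' One tick of extraction for the whole firm population. Each active firm
#' targets \eqn{\max(0, D L c E - B_r)} using its demand from the previous
#' tick. Extraction is bounded by the stock of the firm's patch; when
#' several firms share a patch the available stock is rationed pro rata.
#' Protected patches are never extracted. Firms standing on a depleted or
#' protected patch relocate (when \code{relocate_when_depleted} is set) to
#' the richest unprotected patches, ties broken by lowest patch id, one
#' firm per patch in randomized activation order. Extraction cost is then
#' charged through the investment rule and paid out to the household sector
#' as operational expenditure.
#'
#' @param firms the firm data frame.
#' @param patches the patch data frame.
#' @param econ the \code{economy} configuration section.
#' @param agd_prev previous-tick aggregate demand (for the investment
#'   cost).
#' @return a list: updated \code{firms} and \code{patches}, per-firm
#'   \code{extracted}, total \code{investment} charged.
#' @export
extract_resources <- function(firms, patches, econ, agd_prev = 0) {
  n <- nrow(firms)
  extracted <- numeric(n)
  act <- which(!firms$bankrupt)
  if (length(act)) {
    ord <- if (length(act) > 1) sample(act) else act
    # relocation off dead or protected ground
    if (isTRUE(econ$relocate_when_depleted)) {
      here <- firms$patch[ord]
      needs <- patches$stock[here] <= 0 | patches$protected[here]
      movers <- ord[needs]
      if (length(movers)) {
        pool <- which(patches$stock > 0 & !patches$protected)
        if (length(pool)) {
          pool <- pool[order(-patches$stock[pool], patches$patch_id[pool])]
          take <- seq_len(min(length(movers), length(pool)))
          firms$patch[movers[take]] <- pool[take]
        }
      }
    }
    target <- extraction_target(firms$demand_prev[act], firms$labour[act],
                                econ$conversion_factor,
                                firms$tech_eff[act], firms$reserve[act])
    # harvesting is an expense: firms extract only what they can pay for
    if (econ$extraction_unit_cost > 0) {
      target <- pmin(target, pmax(firms$capital[act], 0) /
                       econ$extraction_unit_cost)
    }
    loc <- firms$patch[act]
    open <- !patches$protected[loc]
    target[!open] <- 0
    tot <- tapply(target, loc, sum)
    avail <- patches$stock[as.integer(names(tot))]
    frac <- ifelse(tot > 0, pmin(1, avail / tot), 0)
    got <- target * frac[match(as.character(loc), names(tot))]
    extracted[act] <- got
    drawn <- tapply(got, loc, sum)
    pids <- as.integer(names(drawn))
    patches$stock[pids] <- pmax(0, patches$stock[pids] - as.numeric(drawn))
    hit <- act[got > 0]
    patches$harvested[firms$patch[hit]] <- TRUE
    patches$last_harvester[firms$patch[hit]] <- firms$firm_id[hit]
    firms$reserve[act] <- firms$reserve[act] + got
    firms$capital[act] <- firms$capital[act] -
      got * econ$extraction_unit_cost
  }
  invest <- numeric(n)
  invest[act] <- pmin(
    investment_required(agd_prev, firms$labour[act], firms$capital[act],
                        econ$correction_factor),
    pmax(firms$capital[act], 0)
  )
  firms$capital <- firms$capital - invest
  list(firms = firms, patches = patches, extracted = extracted,
       investment = sum(invest) +
         sum(extracted) * econ$extraction_unit_cost)
}

#' Firm pricing
#'
#' The price rule evaluated with a configuration's floors:
#' \eqn{P = D \max(P_k, p_0)/\max(B_r, b_0)}.
#'
#' @param demand firm-level goods demand this tick.
#' @param speculation the current speculation index \eqn{P_k}.
#' @param reserve the firm's biomass reserve.
#' @param econ the \code{economy} configuration section.
#' @return a strictly positive price.
#' @export
set_price <- function(demand, speculation, reserve, econ) {
  pmax(price_rule(demand, speculation, reserve,
                  econ$speculation_price_floor, econ$reserve_floor),
       econ$price_min)
}

#' Goods sales with proportional rationing
#'
#' Sells one firm's goods to a set of buyers. Supply in goods is the
#' biomass reserve converted at the factor \eqn{c} (extraction technology
#' raises how much firms harvest, not how far a unit of biomass stretches);
#' when demand exceeds supply every buyer is rationed proportionally. Each
#' buyer's spending is additionally capped by its spendable money. Money
#' moves exactly: the sum of buyer payments equals firm revenue, and the
#' biomass drawn from the reserve is \code{goods / c}.
#'
#' @param demands per-buyer goods demand (non-negative).
#' @param reserve the firm's biomass reserve.
#' @param price the goods price.
#' @param conversion conversion factor \eqn{c} (goods per biomass unit).
#' @param spendable per-buyer spendable money (defaults to no cap).
#' @return a list: \code{goods} and \code{spend} per buyer, firm
#'   \code{revenue}, and \code{biomass_used}.
#' @export
sell_goods <- function(demands, reserve, price, conversion,
                       spendable = rep(Inf, length(demands))) {
  if (any(demands < 0)) stop("negative demand", call. = FALSE)
  supply <- reserve * conversion
  total <- sum(demands)
  alloc <- if (total > supply && total > 0) {
    demands * supply / total
  } else {
    demands
  }
  goods <- pmin(alloc, pmax(spendable, 0) / price)
  spend <- goods * price
  list(goods = goods, spend = spend, revenue = sum(spend),
       biomass_used = sum(goods) / conversion)
}

#' Firm productivity
#'
#' @param capital,capital_prev firm capital now and one tick ago.
#' @param labour workforce size; a firm with no workers reports zero
#'   productivity by convention.
#' @return productivity per worker.
#' @export
compute_productivity <- function(capital, capital_prev, labour) {
  productivity_rule(capital, capital_prev, labour)
}

#' Wage payment
#'
#' Computes the payroll for one or more firms: per-worker wage
#' \eqn{W_n = W_c F_c / L} and total payroll \eqn{W_c F_c}. Firms with
#' non-positive capital pay nothing (and release their workers in the
#' scheduler).
#'
#' @param capital firm capital.
#' @param labour workforce size.
#' @param econ the \code{economy} configuration section.
#' @return a list with per-firm \code{wage} and \code{payroll}.
#' @export
pay_wages <- function(capital, labour, econ) {
  pays <- capital > 0 & labour > 0
  payroll <- ifelse(pays, econ$wage_coefficient * capital, 0)
  wage <- ifelse(pays, payroll / pmax(labour, 1), 0)
  list(wage = wage, payroll = payroll)
}

#' Technology investment
#'
#' Firms plough a fraction of their capital growth — trading profits plus
#' freshly borrowed credit — into extraction technology; efficiency rises
#' by \code{tech_efficiency_gain} per money unit spent. Investment rides
#' the upswing: firms that are shrinking do not invest, so rapid
#' (credit-financed) capital growth is what accelerates technological
#' development. The spend is deducted from firm capital (and is returned
#' so the scheduler can recycle it to the household sector as R&D
#' expenditure).
#'
#' @param firms the firm data frame.
#' @param econ the \code{economy} configuration section.
#' @param tech_cap optional policy cap on the investment fraction.
#' @return a list: updated \code{firms} and total \code{spend}.
#' @export
invest_in_technology <- function(firms, econ, tech_cap = NULL) {
  frac <- econ$tech_investment_fraction
  if (!is.null(tech_cap)) frac <- min(frac, tech_cap)
  act <- !firms$bankrupt
  spend <- ifelse(act,
                  frac * pmin(pmax(firms$capital - firms$capital_prev, 0),
                              pmax(firms$capital, 0)),
                  0)
  firms$tech_eff <- firms$tech_eff + econ$tech_efficiency_gain * spend
  firms$capital <- firms$capital - spend
  list(firms = firms, spend = sum(spend))
}

#' Credit lending
#'
#' The bank grants a loan if the amount does not exceed its lending
#' capacity (the lendable reserve stock) and the borrower passes the
#' creditworthiness rule: post-loan debt-to-capital at or below the
#' configured cap. Refusal is a normal outcome. On a grant the borrower's
#' capital rises by the amount (credit money creation), the bank's lendable
#' reserves fall by it, and a new ledger entry is opened at the credit
#' interest rate over the configured term.
#'
#' @param bank the bank list.
#' @param amount requested principal (positive).
#' @param borrower_capital,borrower_debt the borrower's current capital and
#'   outstanding debt.
#' @param econ the \code{economy} configuration section.
#' @param borrower_type,borrower ledger identification of the borrower.
#' @return a list: \code{granted} flag, \code{bank}, and the new
#'   \code{loan} row (or \code{NULL} on refusal).
#' @export
bank_lend <- function(bank, amount, borrower_capital, borrower_debt, econ,
                      borrower_type = "firm", borrower = 1L) {
  stopifnot(amount > 0)
  worthy <- (borrower_debt + amount) /
    max(borrower_capital, econ$credit_assessment_floor) <=
    econ$debt_to_capital_cap
  if (amount > bank$reserves || !worthy) {
    return(list(granted = FALSE, bank = bank, loan = NULL))
  }
  bank$reserves <- bank$reserves - amount
  loan <- data.frame(
    loan_id = NA_integer_, borrower_type = borrower_type,
    borrower = as.integer(borrower), principal = amount, balance = amount,
    rate = econ$credit_interest_rate,
    ticks_remaining = as.integer(econ$loan_term)
  )
  list(granted = TRUE, bank = bank, loan = loan)
}

#' Credit repayment for one borrower
#'
#' Processes one tick of amortization across all of a borrower's loans.
#' Each loan falls due its equal-principal installment plus interest on the
#' outstanding balance. If the borrower cannot cover the total due it pays
#' what it can, pro rata across loans (interest and principal in
#' proportion). A borrower whose capital ends below the bankruptcy floor
#' while still short — and with no biomass reserve left to trade its way
#' out (\code{reserve}, zero for speculators) — defaults: every remaining
#' balance is written off to the bank's bad debt and charged against the
#' bank's interest surplus, so lending capacity shrinks. Loans that reach
#' the end of their term with a residual balance are likewise written off.
#'
#' @param loans the borrower's ledger rows.
#' @param capital the borrower's capital.
#' @param bank the bank list.
#' @param econ the \code{economy} configuration section.
#' @param reserve the borrower's biomass reserve, if any; an insolvent
#'   borrower that still holds a sellable reserve is squeezed, not
#'   liquidated.
#' @param liquidate whether sustained insolvency triggers liquidation this
#'   tick; the scheduler liquidates firms only after several consecutive
#'   distressed ticks, while speculators fail immediately.
#' @return a list: updated \code{loans}, \code{capital}, \code{bank},
#'   flows \code{principal_paid}, \code{interest_paid},
#'   \code{written_off}, and a \code{defaulted} flag.
#' @export
repay_credits <- function(loans, capital, bank, econ, reserve = 0,
                          liquidate = TRUE) {
  if (nrow(loans) == 0 || sum(loans$balance) <= 0) {
    return(list(loans = loans, capital = capital, bank = bank,
                principal_paid = 0, interest_paid = 0, written_off = 0,
                defaulted = FALSE, distressed = FALSE))
  }
  inst <- loan_installment(loans$balance, loans$ticks_remaining,
                           loans$rate)
  due <- sum(inst$total)
  pay <- min(due, max(capital, 0))
  phi <- if (due > 0) pay / due else 0
  principal_paid <- phi * sum(inst$principal)
  interest_paid <- phi * sum(inst$interest)
  loans$balance <- loans$balance - phi * inst$principal
  loans$ticks_remaining <- pmax(loans$ticks_remaining - 1L, 0L)
  capital <- capital - pay
  bank$equity <- bank$equity + interest_paid
  written_off <- 0
  distressed <- phi < 1 && capital < econ$bankruptcy_floor &&
    reserve <= econ$reserve_floor
  defaulted <- distressed && liquidate &&
    reserve <= econ$reserve_floor
  if (defaulted) {
    written_off <- sum(loans$balance)
    loans$balance <- 0
  } else {
    expired <- loans$ticks_remaining == 0L & loans$balance > 1e-9
    if (any(expired)) {
      written_off <- sum(loans$balance[expired])
      loans$balance[expired] <- 0
    }
  }
  if (written_off > 0) {
    bank$bad_debt <- bank$bad_debt + written_off
    bank$equity <- bank$equity - written_off
  }
  loans <- loans[loans$balance > 1e-12, , drop = FALSE]
  list(loans = loans, capital = capital, bank = bank,
       principal_paid = principal_paid, interest_paid = interest_paid,
       written_off = written_off, defaulted = defaulted,
       distressed = distressed)
}

#' Bank accounting
#'
#' Partitions household deposits per the cash reserve ratio: the
#' ratio-determined share is withdrawable capital (available to households
#' for consumption), the remainder plus any positive interest surplus —
#' net of credit already outstanding — is the lendable reserve stock.
#' Under a full-reserve system (ratio 1) the whole deposit base is
#' withdrawable and lending capacity comes from the interest surplus only.
#' Deposit interest is then paid to households out of the (non-negative
#' part of the) surplus.
#'
#' @param bank the bank list.
#' @param household_capital vector of household balances (deposits).
#' @param outstanding total credit principal currently outstanding.
#' @param econ the \code{economy} configuration section.
#' @return a list: updated \code{bank}, per-household
#'   \code{interest_paid}, and \code{deposits}.
#' @export
bank_accounting <- function(bank, household_capital, outstanding, econ) {
  if (any(household_capital < -1e-6)) {
    stop("negative household deposits", call. = FALSE)
  }
  household_capital <- pmax(household_capital, 0)
  deposits <- sum(household_capital)
  ratio <- bank$cash_reserve_ratio
  bank$withdrawable <- ratio * deposits
  bank$reserves <- max(0, (1 - ratio) * deposits +
                         max(bank$equity, 0) - outstanding)
  due <- econ$deposit_interest_rate * household_capital
  payable <- min(sum(due), max(bank$equity, 0))
  phi <- if (sum(due) > 0) payable / sum(due) else 0
  paid <- phi * due
  bank$equity <- bank$equity - sum(paid)
  list(bank = bank, interest_paid = paid, deposits = deposits)
}

#' Speculator betting step
#'
#' Settles last tick's derivative bets against the realized mean-price
#' change (the bank's trading book is the counterparty, so bets conserve
#' money), then places new credit-funded bets. Speculators enter only while
#' both prices and GDP are rising; each active speculator borrows a
#' configurable fraction of its capital and stakes it on continued price
#' rises. A speculator whose capital has fallen below the bankruptcy floor
#' while conditions no longer invite further borrowing turns inactive; its
#' debt is written off through the repayment step.
#'
#' @param specs the speculator data frame.
#' @param market the market list (uses \code{mean_price},
#'   \code{mean_price_prev}, \code{price_rising}, \code{gdp_rising}).
#' @param bank the bank list.
#' @param loans the loan ledger.
#' @param econ the \code{economy} configuration section.
#' @param blocked \code{TRUE} when government policy blocks new speculative
#'   borrowing.
#' @return a list: updated \code{specs}, \code{bank}, \code{loans},
#'   credit \code{granted} this tick, and net \code{settled} winnings.
#' @export
speculator_step <- function(specs, market, bank, loans, econ,
                            blocked = FALSE) {
  granted <- 0
  settled <- 0
  act <- which(specs$active)
  # settle open bets at the realized relative price change
  open <- act[specs$stake[act] > 0]
  if (length(open) && market$mean_price_prev > 0) {
    q <- (market$mean_price - market$mean_price_prev) /
      market$mean_price_prev
    gain <- specs$stake[open] * q
    specs$capital[open] <- specs$capital[open] + gain
    bank$equity <- bank$equity - sum(gain)
    settled <- sum(gain)
  }
  specs$stake[specs$active] <- 0
  rising <- isTRUE(market$price_rising) && isTRUE(market$gdp_rising)
  if (rising && !blocked) {
    sdebt <- loans$balance[loans$borrower_type == "speculator"]
    swho <- loans$borrower[loans$borrower_type == "speculator"]
    new_amt <- numeric(0)
    new_who <- integer(0)
    for (i in act) {
      want <- econ$spec_borrow_fraction * max(specs$capital[i],
                                              econ$min_loan)
      if (want < econ$min_loan || want > bank$reserves) next
      debt_i <- sum(sdebt[swho == specs$spec_id[i]])
      worthy <- (debt_i + want) /
        max(specs$capital[i], econ$credit_assessment_floor) <=
        econ$debt_to_capital_cap
      if (!worthy) next
      bank$reserves <- bank$reserves - want
      specs$capital[i] <- specs$capital[i] + want
      specs$stake[i] <- want
      new_amt <- c(new_amt, want)
      new_who <- c(new_who, specs$spec_id[i])
      granted <- granted + want
    }
    if (length(new_amt)) {
      loans <- rbind(loans, data.frame(
        loan_id = NA_integer_, borrower_type = "speculator",
        borrower = new_who, principal = new_amt, balance = new_amt,
        rate = econ$credit_interest_rate,
        ticks_remaining = as.integer(econ$loan_term)
      ))
    }
  } else {
    # a squeezed speculator unwilling to borrow further goes under
    broke <- act[specs$capital[act] < econ$bankruptcy_floor]
    specs$active[broke] <- FALSE
  }
  list(specs = specs, bank = bank, loans = loans, granted = granted,
       settled = settled)
}

#' Business expansion
#'
#' Solvent firms open new branch firms on the richest unprotected patches
#' (ties broken by lowest patch id, one branch per patch per tick). A firm
#' expands when its capital — after committing the configured own-capital
#' share — plus an approved expansion loan covers the expansion cost; the
#' new branch is endowed with exactly that cost and inherits the parent's
#' extraction technology. The firm population is capped at
#' \code{max_firm_factor} times the initial count.
#'
#' @param firms the firm data frame.
#' @param patches the patch data frame.
#' @param bank the bank list.
#' @param loans the loan ledger.
#' @param econ the \code{economy} configuration section.
#' @param max_firms hard cap on the firm population.
#' @return a list: updated \code{firms}, \code{bank}, \code{loans}, and
#'   credit \code{granted} for expansions this tick.
#' @export
consider_expansion <- function(firms, patches, bank, loans, econ,
                               max_firms = Inf) {
  granted <- 0
  cost <- econ$expansion_cost
  cand <- which(!firms$bankrupt &
                  firms$capital >= econ$expansion_skin_fraction * cost)
  if (!length(cand) || nrow(firms) >= max_firms) {
    return(list(firms = firms, bank = bank, loans = loans,
                granted = granted))
  }
  pool <- which(patches$stock > 0 & !patches$protected)
  pool <- pool[order(-patches$stock[pool], patches$patch_id[pool])]
  pool <- setdiff(pool, firms$patch)
  ord <- if (length(cand) > 1) sample(cand) else cand
  new_rows <- list()
  for (i in ord) {
    if (nrow(firms) + length(new_rows) >= max_firms || !length(pool)) break
    # expansion is a credit-funded venture: no loan, no new branch
    ask <- max(cost / 2, cost - firms$capital[i], econ$min_loan)
    res <- bank_lend(bank, ask, firms$capital[i], firms$debt[i], econ,
                     borrower_type = "firm", borrower = firms$firm_id[i])
    if (!res$granted) next
    if (firms$capital[i] + ask <= cost) next
    bank <- res$bank
    loans <- rbind(loans, res$loan)
    firms$capital[i] <- firms$capital[i] + ask
    firms$debt[i] <- firms$debt[i] + ask
    granted <- granted + ask
    site <- pool[1]
    pool <- pool[-1]
    firms$capital[i] <- firms$capital[i] - cost
    nf <- firms[i, , drop = FALSE]
    nf$firm_id <- max(firms$firm_id) + length(new_rows) + 1L
    nf$patch <- site
    nf$capital <- cost
    nf$capital_prev <- cost
    nf$labour <- 0L
    nf$reserve <- 0
    nf$productivity <- 0
    nf$wage <- 0
    nf$demand_prev <- 0
    nf$debt <- 0
    nf$distress <- 0L
    nf$bankrupt <- FALSE
    new_rows[[length(new_rows) + 1L]] <- nf
  }
  if (length(new_rows)) firms <- rbind(firms, do.call(rbind, new_rows))
  list(firms = firms, bank = bank, loans = loans, granted = granted)
}
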