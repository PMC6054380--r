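test_that("household demand follows the configured rule", {
  eco <- test_econ(accelerator = 1, distance_decay = 0)
  expect_equal(compute_demand(100, 2, eco), 50)
  expect_equal(compute_demand(0, 2, eco), 0)
  eco2 <- test_econ(accelerator = 1, distance_decay = 0.5)
  expect_equal(compute_demand(100, 2, eco2, distance = 2),
               50 * exp(-1))
})

test_that("extraction is bounded by reserve, stock and protection", {
  eco <- test_econ(conversion_factor = 0.5, extraction_unit_cost = 0,
                   correction_factor = 0, relocate_when_depleted = FALSE)
  patches <- test_patches(c(100, 3))

  # reserve already covers the target: nothing extracted
  f0 <- test_firms(demand_prev = 1, labour = 2L, reserve = 10)
  r0 <- extract_resources(f0, patches, eco)
  expect_equal(r0$extracted, 0)

  # target 6 = 10*2*0.5 - 4, patch holds plenty
  f1 <- test_firms(demand_prev = 10, labour = 2L, reserve = 4)
  r1 <- extract_resources(f1, patches, eco)
  expect_equal(r1$extracted, 6)
  expect_equal(r1$patches$stock[1], 94)
  expect_equal(r1$firms$reserve[1], 10)

  # stock 3 < target 6: extraction bounded by availability
  f2 <- test_firms(patch = 2L, demand_prev = 10, labour = 2L, reserve = 4)
  r2 <- extract_resources(f2, patches, eco)
  expect_equal(r2$extracted, 3)
  expect_equal(r2$patches$stock[2], 0)

  # protected ground is never harvested
  shielded <- test_patches(100, protected = TRUE)
  r3 <- extract_resources(f1, shielded, eco)
  expect_equal(r3$extracted, 0)
  expect_equal(r3$patches$stock, 100)
})

test_that("extraction books a biomass ledger and is funding-limited", {
  eco <- test_econ(conversion_factor = 0.5, extraction_unit_cost = 2,
                   correction_factor = 0, relocate_when_depleted = FALSE)
  # target 20 but capital 10 affords only 5 units at cost 2
  f <- test_firms(capital = 10, demand_prev = 10, labour = 4L, reserve = 0)
  r <- extract_resources(f, test_patches(100), eco)
  expect_equal(r$extracted, 5)
  expect_equal(r$firms$capital[1], 0)
  # patch outflow equals reserve inflow
  expect_equal(100 - r$patches$stock[1], r$firms$reserve[1])
})

test_that("shared patches are rationed pro rata", {
  eco <- test_econ(conversion_factor = 0.5, extraction_unit_cost = 0,
                   correction_factor = 0, relocate_when_depleted = FALSE)
  f <- test_firms(n = 2, patch = 1L, labour = 2L,
                  demand_prev = c(10, 30), reserve = 0)
  # targets 10 and 30 against stock 20: each gets half its target
  r <- extract_resources(f, test_patches(20), eco)
  expect_equal(sort(r$extracted), c(5, 15))
  expect_equal(r$patches$stock[1], 0)
})

test_that("sales ration proportionally and conserve money exactly", {
  none <- sell_goods(c(0, 0), reserve = 100, price = 2, conversion = 0.1)
  expect_equal(none$revenue, 0)
  expect_equal(none$goods, c(0, 0))

  # supply 10 goods, two equal buyers wanting 10 each: 5 apiece
  sale <- sell_goods(c(10, 10), reserve = 100, price = 2,
                     conversion = 0.1)
  expect_equal(sale$goods, c(5, 5))
  expect_equal(sum(sale$spend), sale$revenue) # ledger balances
  expect_equal(sale$biomass_used, 10 / 0.1)

  # a poor buyer is additionally capped by its money
  capped <- sell_goods(c(10, 10), reserve = 100, price = 2,
                       conversion = 0.1, spendable = c(4, 100))
  expect_equal(capped$goods[1], 2) # 4 money / price 2
  expect_equal(capped$spend[1], 4)

  expect_error(sell_goods(c(-1), 10, 1, 0.1), "negative demand")
})

test_that("wages follow the payroll share and vanish for broke firms", {
  eco <- test_econ(wage_coefficient = 0.4)
  w <- pay_wages(100, 8, eco)
  expect_equal(w$wage, 5)
  expect_equal(w$payroll, 40)
  expect_equal(pay_wages(0, 8, eco)$payroll, 0)
  expect_equal(pay_wages(-10, 8, eco)$payroll, 0)
  expect_equal(pay_wages(100, 0, eco)$payroll, 0)
  expect_equal(pay_wages(100, 8, test_econ(wage_coefficient = 0))$wage, 0)
})

test_that("lending respects capacity and creditworthiness", {
  eco <- test_econ()
  bank <- make_bank(eco)
  bank$reserves <- 100

  # beyond capacity: refused, bank untouched
  res <- bank_lend(bank, 200, borrower_capital = 1000, borrower_debt = 0,
                   econ = eco)
  expect_false(res$granted)
  expect_equal(res$bank$reserves, 100)

  # over-leveraged borrower: refused
  res2 <- bank_lend(bank, 10, borrower_capital = 10,
                    borrower_debt = 1000, econ = eco)
  expect_false(res2$granted)

  # grant of 10: reserves fall by 10, loan opens at balance 10
  res3 <- bank_lend(bank, 10, borrower_capital = 100, borrower_debt = 0,
                    econ = eco)
  expect_true(res3$granted)
  expect_equal(res3$bank$reserves, 90)
  expect_equal(res3$loan$balance, 10)
  expect_equal(res3$loan$ticks_remaining, eco$loan_term)
})

test_that("a full-reserve bank with no surplus has zero lending capacity", {
  eco <- test_econ(cash_reserve_ratio = 1, init_bank_equity = 0)
  bank <- make_bank(eco)
  acc <- bank_accounting(bank, household_capital = rep(100, 10),
                         outstanding = 0, econ = eco)
  expect_equal(acc$bank$reserves, 0)
  expect_equal(acc$bank$withdrawable, 1000)
  expect_false(bank_lend(acc$bank, 5, 100, 0, eco)$granted)
})

test_that("bank accounting partitions deposits per the reserve ratio", {
  eco <- test_econ(cash_reserve_ratio = 0.02, init_bank_equity = 0,
                   deposit_interest_rate = 0)
  acc <- bank_accounting(make_bank(eco), rep(100, 10), 0, eco)
  expect_equal(acc$bank$withdrawable, 20)   # 2% withdrawable
  expect_equal(acc$bank$reserves, 980)      # 98% lendable
  expect_equal(acc$deposits, 1000)

  # outstanding credit reduces remaining capacity
  acc2 <- bank_accounting(make_bank(eco), rep(100, 10), 600, eco)
  expect_equal(acc2$bank$reserves, 380)

  expect_error(bank_accounting(make_bank(eco), c(10, -5), 0, eco),
               "negative household deposits")
})

test_that("deposit interest is paid from the surplus only", {
  eco <- test_econ(deposit_interest_rate = 0.01, init_bank_equity = 100)
  acc <- bank_accounting(make_bank(eco), rep(100, 5), 0, eco)
  expect_equal(acc$interest_paid, rep(1, 5))
  expect_equal(acc$bank$equity, 95)
  # broke bank: nothing paid, equity not driven negative
  eco0 <- test_econ(deposit_interest_rate = 0.01, init_bank_equity = 0)
  acc0 <- bank_accounting(make_bank(eco0), rep(100, 5), 0, eco0)
  expect_equal(sum(acc0$interest_paid), 0)
  expect_equal(acc0$bank$equity, 0)
})

test_that("amortization charges equal principal plus interest on balance", {
  eco <- test_econ(bankruptcy_floor = 1)
  bank <- make_bank(eco)
  loan <- data.frame(loan_id = 1L, borrower_type = "firm", borrower = 1L,
                     principal = 100, balance = 100, rate = 0.05,
                     ticks_remaining = 10L)
  rp <- repay_credits(loan, capital = 1000, bank = bank, econ = eco)
  expect_equal(rp$principal_paid + rp$interest_paid, 15) # 10 + 5
  expect_equal(rp$loans$balance, 90)
  expect_equal(rp$capital, 985)
  expect_equal(rp$bank$equity, bank$equity + 5)
  expect_false(rp$defaulted)

  # nothing due on an empty ledger
  none <- repay_credits(loan[0, ], 100, bank, eco)
  expect_equal(none$principal_paid, 0)
})

test_that("an insolvent borrower defaults and its debt becomes bad debt", {
  eco <- test_econ(bankruptcy_floor = 1)
  bank <- make_bank(eco)
  loan <- data.frame(loan_id = 1L, borrower_type = "speculator",
                     borrower = 1L, principal = 100, balance = 100,
                     rate = 0.05, ticks_remaining = 10L)
  rp <- repay_credits(loan, capital = 0.5, bank = bank, econ = eco)
  expect_true(rp$defaulted)
  expect_equal(nrow(rp$loans), 0)
  expect_gt(rp$written_off, 0)
  expect_equal(rp$bank$bad_debt, rp$written_off)
  # the write-off is charged against the bank's surplus
  expect_lt(rp$bank$equity, bank$equity)

  # a squeezed firm with a sellable reserve is spared when not liquidating
  rp2 <- repay_credits(loan, capital = 0.5, bank = bank, econ = eco,
                       reserve = 50, liquidate = FALSE)
  expect_false(rp2$defaulted)
  expect_equal(rp2$written_off, 0)
})

test_that("speculators bet on rising markets and settle against realized
           price moves", {
  eco <- test_econ()
  bank <- make_bank(eco)
  bank$reserves <- 1000
  specs <- make_speculators(list(economy = test_econ(n_speculators = 2L)))
  loans <- ecodebt:::empty_loans()

  flat <- list(mean_price = 10, mean_price_prev = 10,
               price_rising = FALSE, gdp_rising = FALSE)
  s0 <- speculator_step(specs, flat, bank, loans, eco)
  expect_equal(s0$granted, 0) # no bet without a rising market

  rising <- list(mean_price = 11, mean_price_prev = 10,
                 price_rising = TRUE, gdp_rising = TRUE)
  s1 <- speculator_step(specs, rising, bank, loans, eco)
  expect_gt(s1$granted, 0)
  expect_true(all(s1$specs$stake[s1$specs$active] > 0))

  # settlement: stake s against relative change q moves capital by s*q
  s1$specs$stake <- c(100, 0)
  up <- list(mean_price = 12, mean_price_prev = 10,
             price_rising = FALSE, gdp_rising = FALSE)
  s2 <- speculator_step(s1$specs, up, s1$bank, s1$loans, eco)
  expect_equal(s2$specs$capital[1] - s1$specs$capital[1], 100 * 0.2)
  expect_equal(s2$bank$equity, s1$bank$equity - 100 * 0.2)

  # blocked by policy: no new stakes
  s3 <- speculator_step(specs, rising, bank, loans, eco, blocked = TRUE)
  expect_equal(s3$granted, 0)
})

test_that("a broke speculator in a falling market goes inactive", {
  eco <- test_econ(bankruptcy_floor = 1)
  specs <- make_speculators(list(economy = test_econ(n_speculators = 1L)))
  specs$capital <- 0.2
  falling <- list(mean_price = 9, mean_price_prev = 10,
                  price_rising = FALSE, gdp_rising = FALSE)
  out <- speculator_step(specs, falling, make_bank(eco),
                         ecodebt:::empty_loans(), eco)
  expect_false(out$specs$active[1])
})

test_that("expansion picks the richest patch, lowest id on ties, and needs
           credit", {
  eco <- test_econ(expansion_cost = 100, expansion_skin_fraction = 0.5)
  bank <- make_bank(eco)
  bank$reserves <- 1000
  patches <- test_patches(c(50, 80, 80, 10))
  firms <- test_firms(capital = 400)
  loans <- ecodebt:::empty_loans()

  out <- consider_expansion(firms, patches, bank, loans, eco)
  expect_equal(nrow(out$firms), 2)
  expect_equal(out$firms$patch[2], 2) # stock tie at 80: lower id wins
  expect_equal(out$firms$capital[2], 100) # endowed with the cost
  # parent books: capital + loan - endowment
  expect_equal(out$firms$capital[1], 400 + out$granted - 100)
  expect_gt(out$granted, 0)

  # without credit no branch opens
  dry <- make_bank(eco)
  dry$reserves <- 0
  out2 <- consider_expansion(firms, patches, dry, loans, eco)
  expect_equal(nrow(out2$firms), 1)

  # the population cap is respected
  out3 <- consider_expansion(firms, patches, bank, loans, eco,
                             max_firms = 1)
  expect_equal(nrow(out3$firms), 1)
})

test_that("technology investment rides capital growth and never reverses", {
  eco <- test_econ(tech_investment_fraction = 0.5,
                   tech_efficiency_gain = 0.001)
  f <- test_firms(capital = 300)
  f$capital_prev <- 100 # grew by 200: invests 0.5 * 200 = 100
  out <- invest_in_technology(f, eco)
  expect_equal(out$spend, 100)
  expect_equal(out$firms$tech_eff[1], 1.1)
  expect_equal(out$firms$capital[1], 200)

  # shrinking firms sit out
  g <- test_firms(capital = 50)
  g$capital_prev <- 100
  expect_equal(invest_in_technology(g, eco)$spend, 0)

  # a policy cap of zero stops investment entirely
  expect_equal(invest_in_technology(f, eco, tech_cap = 0)$spend, 0)

  # efficiency is non-decreasing across arbitrary histories
  set.seed(5)
  h <- test_firms(capital = 100)
  for (i in 1:20) {
    h$capital_prev <- h$capital
    h$capital <- h$capital + rnorm(1, 0, 50)
    before <- h$tech_eff
    h <- invest_in_technology(h, eco)$firms
    expect_gte(h$tech_eff, before)
  }
})
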