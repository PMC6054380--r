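toy_run <- run_simulation(toy_config(), seed = 42)

test_that("identical configuration and seed give identical runs", {
  again <- run_simulation(toy_config(), seed = 42)
  expect_identical(toy_run$indicators, again$indicators)
  expect_identical(toy_run$audit, again$audit)
  different <- run_simulation(toy_config(), seed = 43)
  expect_false(identical(toy_run$indicators, different$indicators))
})

test_that("the scheduler executes the eleven processes in their fixed
           order", {
  expect_equal(toy_run$process_order,
               c("patches_biomass", "firms_extract", "households_demand",
                 "firms_prices_sales", "firms_labour_finance",
                 "bank_finance", "firms_borrow", "firms_expand",
                 "speculators", "credit_repayment",
                 "government_policies"))
})

test_that("a halted simulation refuses to step", {
  st <- new_simulation(toy_config(), seed = 1)
  st$halted <- TRUE
  expect_error(step_simulation(st), "halted")
})

test_that("an empty world only advances its clock", {
  cfg <- toy_config("economy.n_firms" = 0L, "economy.n_households" = 0L,
                    "economy.n_speculators" = 0L,
                    "environment.initial_stock_per_patch" = 0,
                    "environment.regrowth_rate" = 0)
  st <- new_simulation(cfg, seed = 1)
  before <- st$patches
  st2 <- step_simulation(st)
  expect_equal(st2$tick, 1L)
  expect_equal(st2$patches$stock, before$stock)
  expect_false(st2$halted)
})

test_that("money is stock-flow consistent: only credit creates or destroys
           it", {
  a <- toy_run$audit
  cfg <- toy_run$config
  m0 <- cfg$economy$n_firms * cfg$economy$init_firm_capital +
    cfg$economy$n_households * cfg$economy$init_household_capital +
    cfg$economy$n_speculators * cfg$economy$init_speculator_capital +
    cfg$economy$init_bank_equity
  dm <- diff(c(m0, a$money_total))
  expected <- a$loans_granted - a$principal_repaid -
    a$principal_written_off
  expect_lt(max(abs(dm - expected)), 1e-9)
})

test_that("biomass obeys mass balance at every tick", {
  a <- toy_run$audit
  ind <- toy_run$indicators
  s0 <- toy_run$totals$initial_stock
  ds <- diff(c(s0, ind$natural_resource_stock))
  expected <- a$biomass_growth + a$biomass_restoration -
    a$biomass_extracted
  expect_lt(max(abs(ds - expected)), 1e-9)
})

test_that("the withdrawable stock always equals the reserve-ratio share of
           deposits", {
  for (ratio in c(0.02, 1.0)) {
    run <- run_simulation(toy_config("economy.cash_reserve_ratio" = ratio,
                                     "simulation.horizon" = 50L),
                          seed = 3)
    a <- run$audit
    expect_lt(max(abs(a$withdrawable - ratio * a$deposits)), 1e-9)
  }
})

test_that("collapse detection is strict at the epsilon boundary", {
  st <- new_simulation(toy_config(), seed = 1)
  eps <- st$config$simulation$collapse_epsilon
  st$patches$stock <- rep(eps * st$initial_stock / nrow(st$patches),
                          nrow(st$patches))
  expect_false(detect_collapse(st)) # exactly at the line: not collapsed
  st$patches$stock <- st$patches$stock * 0.999
  expect_true(detect_collapse(st))
  st$patches$stock <- rep(0, nrow(st$patches))
  expect_true(detect_collapse(st))
})

test_that("a zero horizon yields an empty indicator series", {
  run <- run_simulation(toy_config(), seed = 1, horizon = 0)
  expect_equal(nrow(run$indicators), 0)
})

test_that("runs expose indicators under their canonical names", {
  expect_equal(names(toy_run$indicators),
               c("tick", "natural_resource_stock", "real_gdp_growth",
                 "debt_growth_rate", "speculation_rate",
                 "monetary_capital_firms", "monetary_capital_households",
                 "monetary_capital_bank", "technology_efficiency",
                 "mean_price", "employment", "active_speculators"))
  expect_equal(toy_run$indicators$tick, seq_len(nrow(toy_run$indicators)))
  expect_true(all(toy_run$indicators$natural_resource_stock >= 0))
})

test_that("written output round-trips: CSV header and JSON sidecar", {
  csv <- tempfile(fileext = ".csv")
  meta <- tempfile(fileext = ".json")
  write_indicators(toy_run, csv, meta_json = meta)
  back <- utils::read.csv(csv)
  expect_equal(names(back), names(toy_run$indicators))
  expect_equal(nrow(back), nrow(toy_run$indicators))
  info <- jsonlite::read_json(meta)
  expect_equal(info$seed, 42L)
  expect_equal(info$halt_reason, toy_run$halt$reason)
  unlink(c(csv, meta))
})
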