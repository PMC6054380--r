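tiny <- toy_config("simulation.horizon" = 30L)
ens <- run_ensemble(tiny, replicates = 4, base_seed = 21)

test_that("ensemble mean and standard error match a brute-force
           recomputation", {
  for (v in c("natural_resource_stock", "mean_price", "employment")) {
    for (t in c(1, 15, 30)) {
      vals <- sapply(ens$runs, function(r) r$indicators[[v]][t])
      expect_equal(unname(ens$mean[t, v]), mean(vals),
                   tolerance = 1e-12)
      expect_equal(unname(ens$se[t, v]), sd(vals) / sqrt(length(vals)),
                   tolerance = 1e-12)
    }
  }
  expect_equal(ens$survivors, rep(4L, 30))
})

test_that("a single replicate reports its own series with no error band", {
  one <- run_ensemble(tiny, replicates = 1, base_seed = 21)
  solo <- run_simulation(tiny, seed = 21)
  expect_equal(one$mean[, "natural_resource_stock"],
               solo$indicators$natural_resource_stock)
  expect_true(all(is.na(one$se)))
})

test_that("a degenerate constant world has zero error bands", {
  dead <- toy_config("economy.n_firms" = 0L, "economy.n_households" = 0L,
                     "economy.n_speculators" = 0L,
                     "environment.regrowth_rate" = 0,
                     "simulation.horizon" = 10L)
  flat <- run_ensemble(dead, replicates = 3, base_seed = 1)
  expect_true(all(flat$se[, "natural_resource_stock"] == 0))
})

test_that("ensemble summaries are invariant to replicate order", {
  backwards <- ecodebt:::summarize_ensemble(rev(ens$runs),
                                            rev(ens$seeds))
  expect_equal(backwards$mean, ens$mean)
  expect_equal(backwards$se, ens$se)
  expect_equal(sort(backwards$collapse_ticks),
               sort(ens$collapse_ticks))
})

test_that("early-collapsing runs drop out of the per-tick summaries", {
  runs <- ens$runs
  # truncate one replicate as if it had collapsed at tick 10
  runs[[2]]$indicators <- runs[[2]]$indicators[1:10, ]
  runs[[2]]$halt <- list(reason = "resource_collapse", tick = 10L)
  mixed <- ecodebt:::summarize_ensemble(runs)
  expect_equal(mixed$survivors[10], 4L)
  expect_equal(mixed$survivors[11], 3L)
  vals <- sapply(runs[c(1, 3, 4)],
                 function(r) r$indicators$mean_price[20])
  expect_equal(unname(mixed$mean[20, "mean_price"]), mean(vals))
  expect_equal(mixed$regimes[2], "collapse")
  expect_equal(mixed$collapse_ticks[2], 10L)
})

test_that("the OFAT sweep varies exactly one parameter and keeps seeds
           paired", {
  sw <- ofat_sweep(tiny, "economy.credit_interest_rate",
                   values = c(0.03), replicates = 2, base_seed = 21)
  base <- run_ensemble(tiny, replicates = 2, base_seed = 21)
  expect_equal(sw$summaries[[1]]$mean, base$mean) # single value == base
  expect_equal(nrow(sw$table), 1)

  sw3 <- ofat_sweep(tiny, "governance.critical_biomass_fraction",
                    values = c(0, 0.25, 0.5), replicates = 2,
                    base_seed = 21)
  expect_length(sw3$summaries, 3)
  expect_equal(sw3$table$value, c(0, 0.25, 0.5))

  expect_error(ofat_sweep(tiny, "economy.no_such_knob", 1:2, 2, 1),
               "unknown configuration parameter")
})

test_that("runs are classified into collapse, stable and decline regimes", {
  mk <- function(stock) data.frame(
    tick = seq_along(stock), natural_resource_stock = stock
  )
  horizon_halt <- list(reason = "horizon_reached", tick = 100L)

  expect_equal(classify_run(mk(rep(50, 100)),
                            list(reason = "resource_collapse",
                                 tick = 60L)),
               "collapse")
  expect_equal(classify_run(mk(rep(100, 100)), horizon_halt), "stable")
  # monotone decay to 10% of the initial stock without halting
  expect_equal(classify_run(mk(seq(100, 10, length.out = 100)),
                            horizon_halt),
               "decline")
  # held above the stability fraction but still falling: decline
  expect_equal(classify_run(mk(seq(100, 40, length.out = 100)),
                            horizon_halt),
               "decline")
  # recovered and rising at the end: stable
  expect_equal(classify_run(mk(c(seq(100, 30, length.out = 50),
                                 seq(30, 45, length.out = 50))),
                            horizon_halt),
               "stable")
  expect_error(classify_run(mk(numeric(0)), horizon_halt), "empty")
})

test_that("ensemble output files carry the summary and regime tables", {
  scsv <- tempfile(fileext = ".csv")
  rcsv <- tempfile(fileext = ".csv")
  write_ensemble(ens, scsv, rcsv)
  s <- utils::read.csv(scsv)
  expect_equal(nrow(s), 30)
  expect_true("natural_resource_stock_mean" %in% names(s))
  r <- utils::read.csv(rcsv)
  expect_equal(nrow(r), 4)
  expect_true(all(c("credit_issued", "regime", "seed") %in% names(r)))
  unlink(c(scsv, rcsv))
})
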