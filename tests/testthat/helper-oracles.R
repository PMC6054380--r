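# Independent scalar oracles for the behavioural rules, written directly
# from the algebra as plain loops. They deliberately share no code with the
# package internals.

oracle_biocapacity <- function(rs, fy, feq) {
  out <- numeric(length(rs))
  for (i in seq_along(rs)) out[i] <- rs[i] * fy[i] * feq[i]
  out
}

oracle_extraction_target <- function(d, l, c, e, br) {
  out <- numeric(length(d))
  for (i in seq_along(d)) {
    raw <- d[i] * l[i] * c[i] * e[i] - br[i]
    out[i] <- if (raw > 0) raw else 0
  }
  out
}

oracle_demand <- function(hc, p, v, dist, decay) {
  out <- numeric(length(hc))
  for (i in seq_along(hc)) {
    spendable <- max(hc[i], 0)
    d <- spendable / (p[i] * v[i]) * exp(-decay[i] * dist[i])
    cap <- spendable / p[i]
    out[i] <- if (d < cap) d else cap
  }
  out
}

oracle_investment <- function(agd, l, fc, mc) {
  out <- numeric(length(agd))
  for (i in seq_along(agd)) {
    out[i] <- if (fc[i] < 0) 0 else agd[i] * l[i] * fc[i] * mc[i]
  }
  out
}

oracle_price <- function(d, pk, br, pk_floor, br_floor) {
  out <- numeric(length(d))
  pk_floor <- rep_len(pk_floor, length(d))
  br_floor <- rep_len(br_floor, length(d))
  for (i in seq_along(d)) {
    num <- if (pk[i] > pk_floor[i]) pk[i] else pk_floor[i]
    den <- if (br[i] > br_floor[i]) br[i] else br_floor[i]
    out[i] <- d[i] * num / den
  }
  out
}

oracle_productivity <- function(fc, fc_prev, l) {
  out <- numeric(length(fc))
  for (i in seq_along(fc)) {
    out[i] <- if (l[i] > 0) (fc[i] - fc_prev[i]) / l[i] else 0
  }
  out
}

oracle_wage <- function(wc, fc, l) {
  out <- numeric(length(fc))
  for (i in seq_along(fc)) {
    out[i] <- if (l[i] > 0) wc[i] * fc[i] / l[i] else 0
  }
  out
}

oracle_speculation <- function(kg, y) {
  out <- numeric(length(kg))
  for (i in seq_along(kg)) {
    out[i] <- if (kg[i] > 0) kg[i] * y[i] else 0
  }
  out
}

oracle_logistic <- function(s, r, K) {
  grown <- s + r * s * (1 - s / K)
  if (grown > K) K else grown
}

# minimal environment/economy parameter lists for unit tests
test_env <- function(...) {
  env <- list(grid_rows = 4L, grid_cols = 4L, regrowth_rate = 0.1,
              carrying_capacity = 100, initial_stock_per_patch = 100,
              yield_factor = 1.26, equivalence_factor = 1.28,
              restoration_rate = 2, reactivation_fraction = 0.25)
  mods <- list(...)
  for (k in names(mods)) env[[k]] <- mods[[k]]
  env
}

test_econ <- function(...) {
  eco <- default_config(10, 10)$economy
  mods <- list(...)
  for (k in names(mods)) eco[[k]] <- mods[[k]]
  eco
}

# bare patch table for environment tests
test_patches <- function(stock, protected = FALSE, restoring = FALSE) {
  n <- length(stock)
  data.frame(patch_id = seq_len(n), row = rep(0L, n), col = seq_len(n) - 1L,
             stock = stock, protected = rep_len(protected, n),
             restoring = rep_len(restoring, n), harvested = rep(FALSE, n),
             last_harvester = rep(NA_integer_, n))
}

# bare firm table for economy tests
test_firms <- function(n = 1, patch = 1L, capital = 100, labour = 2L,
                       reserve = 0, demand_prev = 0, tech_eff = 1) {
  data.frame(firm_id = seq_len(n), patch = rep_len(patch, n),
             capital = rep_len(capital, n),
             capital_prev = rep_len(capital, n),
             labour = rep_len(as.integer(labour), n),
             reserve = rep_len(reserve, n), price = rep(1, n),
             productivity = rep(0, n), wage = rep(0, n),
             tech_eff = rep_len(tech_eff, n),
             demand_prev = rep_len(demand_prev, n), debt = rep(0, n),
             distress = rep(0L, n), bankrupt = rep(FALSE, n))
}
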