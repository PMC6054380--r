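---
title: "ecodebt: model and methods"
author: "ecodebt authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ecodebt: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecodebt)
```

## The system being simulated

`ecodebt` couples a monetary-circuit, debt-based economy to a renewable
biological resource. The landscape is a rectangular grid of land parcels
(patches), each holding a biomass stock $R_s$ that regrows logistically
toward a carrying capacity $K$. The economy consists of heterogeneous
firms that extract biomass, convert it to a single consumption good and
sell it to households; households that supply labour, earn wages and
spend deposits on goods; one commercial bank with a dual balance sheet
(withdrawable capital vs lendable reserves) that creates credit money by
lending; and speculators that borrow to bet on goods-price movements
without ever trading the good itself. A government can activate a package
of conservation policies once the total resource stock falls below a
critical fraction of its initial level.

The question the simulator is built to explore is how the *banking
regime* — fractional-reserve (cash reserve ratio 0.02) versus
full-reserve (ratio 1) — and the *timing of conservation policy*
(intervention thresholds at 50% or 25% of the initial stock, or never)
shape the fate of the resource base: sustained use, decline, or outright
collapse, defined as the total stock falling below 1% of its initial
value.

## Behavioural rules

Each agent's behaviour is driven by a small set of algebraic rules,
exposed as pure functions so they can be audited independently of the
scheduler:

| rule | form | role |
|---|---|---|
| biocapacity | $B = R_s F_y F_{eq}$ | productive capacity of a patch |
| extraction | $R_e = \max(0,\, D L c E - B_r)$ | biomass a firm harvests |
| demand | $D = \dfrac{H_c}{P v} e^{-\lambda d}$ | household goods demand |
| investment | $K = AGD_{t-1} L F_c M_c$ | extraction-cost overhead |
| price | $P = \dfrac{D \max(P_k, p_0)}{\max(B_r, b_0)}$ | goods price |
| productivity | $p = (F_c(t) - F_c(t-1))/L$ | per-worker effectiveness |
| nominal wage | $W_n = W_c F_c / L$ | payroll share per worker |
| speculation | $P_k = \max(k_g, 0)\, Y$ | speculative price pressure |

Here $E$ is the firm's extraction-technology efficiency, $B_r$ its
standing biomass reserve, $H_c$ household capital, $v$ the demand
accelerator, $\lambda$ the distance-decay coefficient, $k_g$ the
(price-deflated) GDP growth rate and $Y$ real output. One tick is read as
one year: productivity compares capital "from one year to the next".

Three points about how the rules interlock deserve emphasis, because they
carry the scenario contrasts:

* **Technology amplifies extraction, not conversion.** Efficiency $E$
  multiplies the harvest target only. Conversion of biomass to goods uses
  the fixed factor $c$, so one good always embodies $1/c$ biomass. If
  efficiency instead stretched conversion, richer technology would
  *reduce* resource use per good and credit-fuelled economies would
  become the most sustainable ones — the opposite of the dynamics the
  model is designed to exhibit.
* **Harvesting is an expense.** Besides the overhead rule $K$, each unit
  of biomass extracted costs a fixed amount of money
  (`extraction_unit_cost`), paid out to the household sector as
  operational labour income. A firm can only harvest what it can pay for,
  which is the hard coupling between credit availability and extraction
  pressure: under full-reserve banking extraction is limited by the
  circulating money stock, under fractional-reserve banking it can be
  financed by freshly created credit.
* **Technology investment rides capital growth.** Firms plough a fraction
  of their capital *growth* — trading profits plus newly borrowed credit
  — into efficiency, which rises linearly with the money spent. Sustained
  exponential efficiency growth therefore requires exponentially growing,
  i.e. credit-financed, spending; a firm financing itself out of a
  stationary cash flow improves slowly and steadily.

## Money and biomass accounting

The simulator enforces strict stock-flow consistency and audits it every
tick:

* **Money** is created only by lending (borrower capital rises, nothing
  falls) and destroyed only by principal repayment and write-offs. Every
  other operation — wages, sales, investment outlays, technology
  spending, deposit and credit interest, speculative settlements,
  restoration fees — is a transfer between firms, households, speculators
  and the bank's equity account. The audit trail records
  $\Delta M = \text{loans} - \text{repayments} - \text{write-offs}$
  and the test suite asserts it to $10^{-9}$ at every tick.
* **Biomass** obeys
  $\Delta S = \text{growth} + \text{restoration} - \text{extraction}$
  patch-exactly. Harvested biomass sits in firm reserves, from which
  sales draw $\text{goods}/c$; reserves also spoil at a small rate
  (`reserve_decay`), which is what keeps extraction pressure tied to the
  *flow* of demand served at a given efficiency rather than saturating
  once reserves fill.
* **The bank's dual balance sheet** is recomputed each tick: the
  ratio-determined share of deposits is withdrawable capital; the
  remainder, plus any non-negative interest surplus, net of credit
  already outstanding, is the lendable reserve stock. Under a ratio of 1
  the whole deposit base is withdrawable and lending capacity comes from
  the interest surplus alone. Speculator and firm defaults write the
  unpaid balance off against that surplus, so bad debt directly destroys
  future lending capacity — the "domino effect" channel from speculative
  bust to credit crunch.

The amortization rule is equal-principal: each tick a loan owes
`balance/ticks_remaining` plus interest on the whole balance. An
insolvent borrower pays what it can, pro rata across its loans. Firms are
liquidated only after `default_patience` (8) consecutive distressed
ticks *and* with an empty biomass reserve — mere illiquidity does not
destroy a firm that still holds sellable stock — whereas speculators,
who hold no productive assets, fail immediately. Loans expiring with a
residual balance are written off.

## The per-tick schedule

Each tick executes eleven processes in fixed order: (i) patches regrow
(logistic) or restore; (ii) firms extract (relocating to the richest
unprotected patches when their own is exhausted, sharing patch stock pro
rata); (iii) households choose a firm (probabilistic discrete choice with
weight $(\text{price} \cdot e^{\lambda d})^{-\gamma}$), move one grid
step toward it, and form demand; (iv) firms set prices (partial
adjustment toward the price rule) and sell with proportional rationing;
(v) firms compute productivity, pay wages, invest in technology, and
hire; (vi) the bank partitions deposits and pays deposit interest from
its surplus; (vii) firms borrow (growth appetite, or a working-capital
line when underfunded); (viii) firms open credit-funded branch firms on
the richest unprotected land; (ix) speculators settle yesterday's bets
against the realized mean-price change (the bank's trading book is the
counterparty, so bets conserve money) and, while both prices and GDP are
rising, stake newly borrowed money; (x) firms and speculators amortize
their loans, with defaults as above; (xi) the government checks its
trigger and applies policy. An indicator row and an audit row are then
recorded and collapse detection runs.

Within-process activation order is randomized each tick from the run's
single seed, so identical `(config, seed)` pairs reproduce byte-identical
output.

## Government intervention

Intervention activates at most once, the first tick the total stock drops
strictly below `critical_biomass_fraction` of the initial stock, and
persists. The policy package is:

1. **Technology restraint** — the investment fraction is capped
   (default cap 0: no further efficiency growth).
2. **Speculation limit** — the speculation index is capped at the level
   prevailing at activation (or the configured cap if higher). Freezing
   rather than zeroing the index stops further speculative amplification
   without engineering a deflation shock that would instantly destroy
   firm revenue.
3. **Protected areas** — the protected network is enlarged by
   `protection_increment` (3% of all patches), drawn uniformly at random
   among unprotected patches; protection is permanent and protected
   patches are never harvested. Random siting means that *late*
   intervention mostly protects already-exhausted land — one of the two
   reasons a 25% trigger fails where a 50% trigger succeeds.
4. **Restoration mandate** — each tick, up to `restoration_capacity` (3)
   patches depleted by harvesting are enrolled for restoration, paid for
   by their last harvester (cost recycled to households as restoration
   labour); enrolled patches gain `restoration_rate` biomass per tick
   and rejoin the ordinary regrowth regime at 25% of capacity. The
   capacity limit reflects that restoration programmes cannot absorb an
   arbitrarily fast wave of depletion.

Extinction is absorbing for unprotected, unrestored land: a patch at zero
stock never regrows on its own. This is what gives the restoration policy
a role and what makes the timing of intervention decisive: at a 50%
trigger the landscape still contains enough live, protectable stock and a
restorable margin; at 25% the harvest rate frozen-in by then (technology
is already several times more efficient) outruns what protection and a
capacity-limited restoration programme can save.

## Scenario presets and the study conditions

The four presets are the study conditions: `fractional_no_gov` (ratio
0.02, no trigger), `fractional_gov25` (trigger 0.25),
`fractional_gov50` (trigger 0.5), and `full_reserve` (ratio 1, no
intervention, since the low-credit economy exerts little pressure).
`run_ensemble()` runs seeded replicates (seeds `base_seed ...
base_seed + n - 1`, shared across scenarios so comparisons are paired)
and summarizes every indicator per tick by the mean and standard error
across surviving runs, with survivor counts reported; 100 replicates is
the reference ensemble size, and the test suite uses 20.

The qualitative regime structure these defaults produce — and which the
acceptance suite verifies by recomputation — is: the unregulated
fractional-reserve economy ends in resource collapse; early intervention
(50%) prevents collapse in every replicate; late intervention (25%)
fails in part of the ensemble and leaves the rest in steep decline; the
full-reserve economy never collapses and issues orders of magnitude less
credit, with a boom–bust (rise-then-fall) signature in speculation and
debt growth preceding collapse in the unregulated runs.

## Parameters

All coefficients live in a four-section configuration
(`environment`/`economy`/`governance`/`simulation`; see
`default_config()`). The defaults are this package's own calibration,
chosen once so that the documented regime structure emerges, and are
deliberately configurable. The ones that matter most:

* `regrowth_rate` 0.08/tick and `carrying_capacity` 100 per patch, with
  pristine initial stock at capacity; `yield_factor` 1.26 and
  `equivalence_factor` 1.28 are forest-land placeholders from
  ecological-footprint accounting and feed only the biocapacity
  indicator.
* `conversion_factor` c = 0.35 balances harvest against sales at baseline
  efficiency ($Lc \approx 1/c$ at the 4-worker firm size), so technology
  growth — not an arbitrary unit mismatch — is what creates overharvest.
* `credit_interest_rate` 0.03/tick over a 10-tick equal-principal term,
  `deposit_interest_rate` 0.005/tick (the spread is the bank's income),
  `borrow_appetite` 0.4 of capital per tick, creditworthiness cap of 5
  on debt over assessed capital (floored at `credit_assessment_floor`
  20 so lending lines are sized against firm scale, not instantaneous
  cash).
* `tech_investment_fraction` 0.5 of capital growth,
  `tech_efficiency_gain` 0.03 efficiency per money unit.
* Agent densities per patch: 0.5% firms, 8% households, 0.2%
  speculators, so economic pressure scales with the landscape and the
  dynamics are approximately grid-size invariant.

## Numerical choices and degenerate cases

The price rule's divisions are guarded (`reserve_floor` 1, the
speculation floor 1, `price_min`), prices adjust partially
(`price_adjust` 0.15) toward the rule, firms form adaptive demand
expectations (`demand_smoothing` 0.5), and the growth rate feeding the
speculation rule is computed on price-deflated GDP and clamped to ±20%
per tick — raw nominal growth rates from near-zero bases otherwise
interact with the price rule to produce astronomically large price
spikes. Collapse detection and the policy trigger are strict
inequalities, and a horizon of zero returns an empty, valid series.
Ties in patch selection break toward the lowest patch id.

## What the scenarios do and do not emulate

The presets generate the full range of behaviour the simulator is tested
on: credit booms, speculative bubbles and busts, mass bankruptcy, credit
crunches, landscape depletion, policy-triggered stabilization. They do
not emulate features of real coupled systems such as heterogeneous land
cover, multiple good types, household or government borrowing,
inter-bank markets, stochastic environmental shocks, or empirically
estimated behavioural parameters. Passing tests therefore demonstrate
internal consistency and the claimed qualitative regime structure under
the documented conditions — not calibrated predictions for any real
economy or ecosystem.

## Problem sizes

The package's reference experiments use a 50 × 50 landscape with 20
replicates per scenario over the default 250-tick horizon; a single run
completes in about two seconds, a four-scenario ensemble comparison in
about two minutes. The 100 × 100 default landscape is the headline
configuration for standalone runs; densities keep the dynamics
comparable across sizes.

## Known limitations

Within-tick market clearing is sequential rather than simultaneous, so
very large single-tick shocks can momentarily misprice goods; the
demand–price interaction retains a damped endogenous oscillation that is
visible in most indicator series; firm relocation is informed (richest
patch first) while household search is local and probabilistic, an
asymmetry that speeds landscape depletion; and the speculative
settlement treats the bank as the universal counterparty, which folds
all derivative losses into bank equity rather than a separate clearing
sector.
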