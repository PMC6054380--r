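# ecodebt

An agent-based simulator of a **debt-based economy coupled to a renewable
resource landscape**, for researchers in ecological economics and
social-ecological systems who want to experiment with how banking regimes
and conservation policy shape resource sustainability.

The economy is a monetary circuit in the tradition of debt-based
macroeconomic models: firms finance production with bank credit,
households supply labour and demand, a commercial bank holds a dual
balance sheet (withdrawable capital vs lendable reserves) and creates
money by lending, and speculators borrow to bet on goods prices without
ever trading goods. The environment is a grid of land parcels whose
biomass stock $R_s$ regrows logistically toward a carrying capacity $K$;
extraction is the physical footprint of the economy. A government can
trigger a conservation-policy package (technology-investment caps,
speculation limits, protected-area expansion, mandated restoration) when
the total stock falls below a critical fraction of its initial level.

Agent behaviour is driven by eight algebraic rules:

$$B = R_s F_y F_{eq}, \qquad
  R_e = \max(0,\; D L c E - B_r), \qquad
  D = \frac{H_c}{P v} e^{-\lambda d}, \qquad
  K = AGD_{t-1}\, L\, F_c\, M_c,$$

$$P = \frac{D \max(P_k, p_0)}{\max(B_r, b_0)}, \qquad
  p = \frac{F_c(t) - F_c(t-1)}{L}, \qquad
  W_n = \frac{W_c F_c}{L}, \qquad
  P_k = \max(k_g, 0)\, Y.$$

Money and biomass are conserved exactly: money is created only by
lending and destroyed only by repayment and write-offs; biomass obeys
$\Delta S = \text{growth} + \text{restoration} - \text{extraction}$.
Both ledgers are audited every tick. The methods vignette
(`vignettes/ecodebt-methods.Rmd`) documents the model, every parameter,
and the design decisions in detail.

## A worked example

Run the unregulated fractional-reserve scenario (cash reserve ratio
0.02, no government intervention) on a 50 × 50 landscape:

```r
library(ecodebt)
cfg <- scenario_preset("fractional_no_gov", grid_rows = 50, grid_cols = 50)
run <- run_simulation(cfg, seed = 1)
print(run)
#> <ecodebt_run>
#>   ticks: 164  halt: resource_collapse at 164
#>   final stock: 2204.7 (0.9% of initial)
#>   credit issued: 264018.1  bad debt: 32549.4
```

The credit-fuelled boom drives exponential technology growth and
overharvest; after a speculative boom and bust the resource base drops
below 1% of its initial stock at tick 164 and the run halts with reason
`resource_collapse`. `run$indicators` holds the per-tick series
(resource stock, real GDP growth, debt growth, speculation rate,
sectoral money stocks, technology efficiency, mean price, employment,
active speculators) and `run$audit` the conservation ledger;
`plot(run)` draws the headline series.

Early conservation intervention changes the regime. With policies
triggered at 50% of the initial stock:

```r
ens <- run_ensemble("fractional_gov50", replicates = 5, base_seed = 1,
                    grid_rows = 50, grid_cols = 50)
print(ens)
#> <ecodebt_ensemble> 5 replicates
#>   regimes: decline=5
#>   collapse frequency: 0.00; mean credit issued: 344917.5
```

No replicate collapses: the landscape stabilizes (at reduced stock)
instead of being exhausted. `ofat_sweep()` varies one configuration
parameter at a time across such ensembles, and `write_indicators()` /
`write_ensemble()` export CSV series with JSON metadata. The CLI wraps
the same functions:

```sh
Rscript inst/cli/ecodebt.R ensemble --preset fractional_gov50 \
    --replicates 20 --seed 1 --rows 50 --cols 50 --out out/
```

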