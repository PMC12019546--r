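# grazenet

Costing net-zero transitions for grazing livestock farms.

Grazing enterprises face a double exposure: a changing climate that shifts
pasture supply, and climate policy that prices residual greenhouse gas
emissions. grazenet is an R package for farm-systems analysts who want to
ask, for a specific herd or flock: which combinations of interventions —
methane inhibitors, feed-conversion efficiency gains, pasture renovation,
tree planting, income diversification — reach net-zero, what do they cost
per tonne mitigated, and how do they trade off against production and
profit?

The package chains six models behind a tidyverse-style interface (tibbles
in, tibbles out; `tidy()`/`glance()`/`autoplot()` on every result type):

- **Climate**: monthly delta-change projection of historical weather
  (additive temperature deltas, multiplicative rain/evaporation factors,
  CO2 at 350/450/530 ppm for the historical/2030/2050 horizons), plus a
  seeded synthetic weather generator for sites described by summary
  statistics.
- **Production**: a seasonal pasture growth model
  (`G = G_max · f_T(T) · f_W(R,E) · f_CO2(c) · days`) with a monthly feed
  balance closed by supplementary feed, reduced livestock energetics
  (intake demand, product output, an FCE multiplier), and the carbon
  returned to soil as dung, litter and roots by depth layer.
- **Soil carbon**: monthly five-pool turnover (DPM, RPM, BIO, HUM, IOM)
  per depth layer, with temperature/moisture/cover rate modifiers, a
  clay-dependent CO2 split, exact per-step carbon conservation, and a
  closed-form steady state used as a test oracle.
- **Trees**: saturating stand growth `S(t) = p·S_max·(1 − e^(−rt))` with
  diminishing increments, annual removals in Mg CO2e (× 44/12), and ±20%
  perturbation support.
- **Inventory**: a Tier-2-style annual farm inventory — enteric and manure
  CH4, direct and indirect N2O (× 44/28), energy and embedded CO2e —
  converted at GWP100 of 28 (CH4) and 265 (N2O), netted against soil and
  tree sequestration. Net-zero is defined on the 20-year mean of annual
  net emissions after discarding a 6-year spin-up from 26 simulated years.
- **Economics**: correlated-price Monte Carlo (Gaussian copula over
  normal/lognormal/PERT marginals, 10,000 iterations) for operating profit
  (EBIT); a hybrid carbon account (tax $80/Mg CO2e on the positive part of
  mean net emissions, credits $28/Mg on the negative part); marginal
  abatement cost curves; and a normalised multidimensional impact score on
  [0, 3] combining production, profit and inverse-coded emissions.

Interventions are declarative parameter modifications that stack onto a
baseline scenario with full provenance; a shipped catalog provides
low-hanging-fruit, towards-carbon-neutral, income-diversification and four
carbon-neutral bundles for two fixture farms (a 569 ha, 367-cow beef herd
and a 3170 ha, ~24,750-head sheep enterprise).

## Worked example

```r
library(grazenet)

scn  <- scenario(beef_farm_config())
base <- run_scenario(scn, horizon = "2030", seed = 42)
asp  <- run_bundle(scn, "Asp", horizon = "2030", seed = 42)   # seaweed, 80% CH4 cut
cn1  <- run_bundle(scn, "CN1", horizon = "2030", seed = 42)   # Asp + TFCE + 50 ha trees
base
#> <scenario_result> baseline (2030)
#>   production: 213.5 Mg LW, 0.0 Mg wool /yr
#>   pre-tax profit (mean of 10000 draws): $353,971 /yr
#>   mean net emissions: 2219.6 Mg CO2e /yr (net-positive)
#>   carbon account: tax $177,570, credits $0, post-account $176,402
```

The baseline herd emits about 2,220 Mg CO2e per year net (roughly
three-quarters of it enteric methane), and under the hybrid policy the
carbon tax halves its profit. Comparing scenarios:

```r
cmp <- compare_scenarios(list(base, asp, cn1))
cmp$ledger
#>   scenario pre_tax_profit mean_net     tax credit_income post_account_profit
#> 1 baseline        353971.    2220. 177570.            0              176402.
#> 2 Asp             323971.     803.  64212.            0              259759.
#> 3 CN1             259974.    -526.      0         14742.             274716.
tidy(cmp$macc)
#>   scenario abatement cost_per_mg
#> 1 Asp          1417.        21.2
#> 2 CN1          2746.        34.2
```

The seaweed supplement cuts net emissions by ~64% at ~$21 per Mg CO2e
mitigated; the CN1 stack crosses into net-negative territory, swaps the tax
for credit income, and ends up the most profitable option after the carbon
account despite the lowest pre-tax profit. `cmp$scores` carries the
normalised impact totals (baseline 2.00, Asp 2.55, CN1 2.73 here), and
`plot_ternary(cmp$scores)`, `autoplot(cmp$macc)` and
`autoplot(base$profit)` render the standard figures.

Solving the tree area that makes the seaweed scenario exactly net-zero:

```r
nz <- find_net_zero_area(
  stack_interventions(scn, intervention_catalog("Asp", "beef", "2030")),
  horizon = "2030", seed = 42)
nz$area
#> [1] 32.3   # ha of plantation, |20-yr mean net| <= 1 Mg CO2e/yr
```

Run configurations can also be read from YAML
(see `inst/extdata/beef_run.yaml` and `read_run_config()`).

## Documentation

The methods vignette (`vignettes/grazenet-methods.Rmd`) documents each
model, its assumptions and parameters, what the synthetic generators do and
do not emulate, and the package's design decisions and limitations.
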