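---
title: "Models and methods in grazenet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in grazenet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grazenet)
```

grazenet estimates what it costs a grazing livestock enterprise to reach and
hold net-zero greenhouse gas emissions. It chains six models — climate
projection, pasture/livestock production, soil organic carbon turnover, tree
stand sequestration, a farm GHG inventory, and bioeconomic simulation — and
wraps them in an intervention algebra so that adaptation and mitigation
bundles can be stacked onto a baseline farm and compared. This vignette
documents each model, its assumptions, the tunable parameters that matter,
and the design decisions taken where the design was genuinely open.

## Climate: delta scaling with a variability stand-in

The pipeline runs on a monthly cadence because the soil carbon model and the
annual accounting do; daily weather input is aggregated on read (rain and pan
evaporation summed, temperature averaged from the daily midpoints).

Future horizons are built by the delta-change method: for calendar month $m$
of year $y$,

$$T'_{m,y} = T_{m,y} + \Delta T_m, \qquad
  R'_{m,y} = R_{m,y}\, f^R_m\, \max(0,\, 1 + \lambda z_y), \qquad
  E'_{m,y} = E_{m,y}\, f^E_m,$$

with additive monthly temperature deltas, multiplicative rain and evaporation
factors, and atmospheric CO$_2$ fixed at 350 / 450 / 530 ppm for the
historical, 2030 and 2050 horizons. The $\lambda z_y$ term ($z_y$ a seeded
standard normal shared by all months of year $y$) widens interannual rainfall
spread without reshaping the seasonal profile. It is deliberately a simple
stand-in for full stochastic extreme-event generators, which need
sub-monthly structure this package does not model; it should not be read as a
reimplementation of any of them. The historical horizon uses identity
factors, which is tested as an exact identity on the weather fields.

The synthetic historical generator draws annual rainfall totals from a
normal distribution (clamped at zero — negligible at the shipped sites, where
the coefficient of variation is about 0.2) and splits them over months by a
seasonal fraction profile with multiplicative jitter renormalised to
preserve the annual total exactly. Two site presets are shipped: a
high-rainfall coastal site (807 ± 139 mm) and a low-rainfall midlands site
(499 ± 103 mm), with matching seasonal temperature and pan-evaporation
profiles. Humidity, solar radiation and wind are not generated; nothing
downstream consumes them.

## Synthetic farm production

The production generator stands in for a daily pasture/livestock simulator.
Its contract with the rest of the pipeline is deliberately narrow: the
downstream inventory and economics depend only on intake, head counts,
product masses and the carbon returned to soil, so livestock energetics are
reduced to three levers per stock class — intake demand (kg DM head$^{-1}$
day$^{-1}$), annual product output per head, and a farm-level
feed-conversion-efficiency (FCE) multiplier.

Monthly pasture growth is

$$G = G_{\max} \cdot f_T(\bar T)\cdot f_W(R, E)\cdot f_{CO_2}(c) \cdot d,$$

with a trapezoidal temperature response, water stress
$f_W = \min(1, R / (w\,E))$, and CO$_2$ fertilisation
$f_{CO_2} = 1 + \beta \ln(c/350)$. The $\beta$ defaults (0.06 beef sward,
0.18 sheep sward) were chosen once so the 530 ppm horizon lifts annual
growth by roughly 2–3% and 7–8% respectively — the modest percent-scale
response expected of temperate pastures — and are not revisited.

The feed balance closes monthly: demand is
$\sum_c h_c\, \mathrm{dmi}_c / \mathrm{FCE}$ scaled by days; consumed
pasture is the lesser of demand and utilisable growth
(growth × area × utilisation); supplement makes up the deficit, so consumed
plus supplement equals demand whenever demand is positive. A single balance
rule replaces farm-specific maintenance-versus-production feeding rules —
a declared simplification. The FCE multiplier divides intake at fixed
product output (not the converse), because that is how efficiency gains
reduce enteric methane in the inventory.

Carbon returns per hectare are: dung C = intake × (1 − digestibility) ×
carbon fraction; litter C = ungrazed residue × litter fraction × carbon
fraction; root C = shoot production × root:shoot × carbon fraction, split
between depth layers by the configured root fractions. Defaults
(digestibility 0.7, carbon fraction 0.4, root:shoot 0.45, litter fraction
0.4) give total returns of 3–4 Mg C ha$^{-1}$ yr$^{-1}$ on the productive
fixture farm, a realistic flux for improved temperate pasture.

Two fixture configurations ship with the package: a 569 ha beef herd (367
cows plus followers and trade stock) and a 3170 ha sheep enterprise
(roughly 24,750 head in two flocks plus a small cattle herd). They are
calibrated to printed herd magnitudes and to realistic emission and profit
structure — enteric methane is roughly three quarters of gross emissions,
and soil accrual is a minor term — without claiming to reproduce any real
farm. What passing tests show is that the *relationships* the analysis
depends on (feed balance closure, carbon mass balance, monotone responses)
hold; they do not show agreement with any particular commercial enterprise,
and real data would add between-animal variation, feed carry-over and
pasture composition dynamics the generator omits.

## Soil organic carbon: monthly five-pool turnover

Soil carbon follows the classical five-pool monthly turnover scheme:
decomposable plant material (DPM), resistant plant material (RPM), microbial
biomass (BIO), humified organic matter (HUM) and inert organic matter (IOM),
run independently for two layers (0–30 cm and 30–100 cm). Each active pool
decays in a month by $P(1 - e^{-k\,abc/12})$ with rate constants $k$ in
yr$^{-1}$: 10, 0.17, 0.66, 0.02 (top layer) and 0.33, 0.01, 0.02, 0.00
(deep layer) for DPM, RPM, BIO, HUM. The zero deep-layer HUM constant makes
deep humus inert; it is treated literally, and the closed-form steady state
reports such a pool as non-convergent whenever it has a positive inflow.

The rate modifiers follow the published description of the model version
named above: temperature
$a = 47.91 / (1 + e^{106.06/(\bar T + 18.27)})$; moisture $b$ piecewise
linear between 1 and 0.2 in the accumulated topsoil moisture deficit, whose
maximum is $-(20 + 1.3\,\mathrm{clay} - 0.01\,\mathrm{clay}^2)$ mm scaled by
layer depth over 23 cm, updated monthly by rain − 0.75 × pan evaporation;
and soil cover $c = 0.6$ under pasture. Decomposed carbon splits between
respired CO$_2$ and (BIO + HUM) in the ratio $x:1$ with
$x = 1.67(1.85 + 1.60\,e^{-0.0786\,\mathrm{clay}})$, and the retained share
partitions 46% BIO / 54% HUM. Carbon is conserved exactly at every step and
property-tested to 10$^{-9}$ relative over randomised states.

Initial pools place 1% of initial SOC in DPM and 2.2% in BIO. The source
description lists fast and slow microbial fractions (2% + 0.2%) while the
standard model carries one biomass pool; the package keeps a single BIO pool
initialised at their sum — an explicit deviation that would be revisited if
distinct sub-pool rates surfaced. The RPM/HUM split of the non-inert
remainder is a configuration parameter (`rpm_frac_rem`, default 0.12),
because the regional pool-fraction data that would pin it down is not
shipped. Fresh plant carbon enters DPM:RPM at 1.44 (the grassland
convention); dung enters by its own split (0.49/0.49/0.02 DPM/RPM/HUM),
reflecting partially stabilised manure.

Fixture-farm initial stocks (110 + 55 Mg C ha$^{-1}$ beef, 60 + 30 sheep,
with inert carbon from the empirical power law of total SOC) were placed
near the turnover equilibrium implied by the fixture carbon returns, so the
baseline soil neither gains nor loses implausibly fast. Warming raises the
temperature modifier and therefore respiration, so projected horizons show
reduced accrual — a property the tests assert directionally.

## Tree stands

Stand biomass carbon follows a saturating exponential,
$S(t) = p\, S_{\max}(1 - e^{-rt})$, so annual increments diminish toward a
plateau — the longitudinal behaviour of unharvested plantings. Annual
removals are increments × area × 44/12, reported as positive magnitudes.
The two shipped profiles (plantation eucalypt: 180 Mg C ha$^{-1}$, 0.07
yr$^{-1}$; mixed environmental planting: 110 Mg C ha$^{-1}$, 0.05
yr$^{-1}$) are illustrative temperate calibrations, not the output of a
full carbon-accounting model, and their first-two-decade mean removals sit
in the published range for temperate plantings. No harvesting, fire loss or
grazing beneath trees is modelled, and soil beneath plantings is excluded
so soil and biomass carbon are never double-counted. The ±20% sensitivity
envelope enters as a multiplicative perturbation on increments, making the
removal response exactly linear — which the sweep tests exploit.

## Farm GHG inventory

The inventory assembles seven line items — enteric CH$_4$ (emission factor
per kg of dry-matter intake, by species), manure CH$_4$ (a low
pasture-deposition factor on intake as a volatile-solids proxy), direct
N$_2$O from fertiliser and excreta, indirect N$_2$O via leaching and
volatilisation (N$_2$O-N × 44/28 exactly), energy CO$_2$ (diesel,
electricity) and embedded CO$_2$e (fertiliser manufacture, purchased
feed) — converts them with GWP$_{100}$ of 28 (CH$_4$) and 265 (N$_2$O),
and nets gross emissions against soil and tree sequestration stored as
positive removal magnitudes with explicit subtraction. A year of soil
carbon loss therefore adds to net emissions symmetrically. Emission-factor
defaults are representative of temperate Australian inventory practice
(including a hydro-dominated electricity factor) and are configuration, not
asserted values. N$_2$O from legume biological fixation is excluded.

Net position: 26 simulated years, the first 6 discarded as model spin-up,
and net-zero defined on the 20-year mean of annual net emissions with a
1 Mg CO$_2$e yr$^{-1}$ tolerance (strict equality is unusable with
floating-point means). Emissions intensity allocates net emissions between
meat and wool by protein mass (fractions 0.18 and 0.60), which makes
intensity invariant to splitting a product into sub-lots.

## Interventions

An intervention is a declarative set of parameter modifications (dotted
paths with multiply/add/set modes), economic deltas (capex, annual cost and
income), optional tree stands, and an adoptability attribute — an ordinal
1–5 input supplied by the user, never computed. Bundles are ordered stacks
applied by a left fold; application is pure and appends provenance, so
every parameter differing from baseline is attributable.

Two composition rules deserve note. Enteric inhibitions compose by a *cap*
(maximum of the stacked fractions) by default, because the two shipped
inhibitors — the seaweed feed supplement (80%) and the vaccine (30%) —
target the same rumen pathway and are never bundled together in the shipped
catalog; an independent-action mode ($1 - \prod(1-f_i)$) exists for
exploration. Conflicting `set` modifications on any other path raise a
composition error unless explicitly allowed.

The shipped catalog mirrors the published bundle structure: LHF (management
timing, deeper-rooted pasture, soil fertility, 10%/15% FCE by horizon), TCN
(LHF plus the vaccine, lucerne renovation and tree planting: 50 ha
plantation beef / 200 ha environmental sheep), ID (income diversification),
and four carbon-neutral packages combining the seaweed supplement with
transformational FCE (20%/30%) or lucerne and trees (beef 50 or 55–110 ha;
sheep 200 or 220 ha). Several magnitudes act through mechanisms a daily
simulator would resolve (soil fertility "3%", calving dates); they are
encoded as direct production or cost deltas and flagged as stand-ins.
Lucerne renovation is reduced to four levers: deeper root fraction, higher
legume fraction, a growth uplift and renovation capex. Income
diversification is encoded purely as economic deltas; a purchased land
parcel is not modelled as a second farm unit, because a multi-unit
container would complicate every downstream module for a bundle whose role
in the analysis is economic.

## Economics

Prices are drawn from a Gaussian copula: correlated standard normals
(via the positive-semidefinite square root of the correlation matrix, so a
perfectly correlated pair is legal) mapped through each marginal's inverse
CDF. Marginal families are normal, lognormal and PERT (the four-parameter
beta convention with shape 4); livestock product prices are correlated at
0.6 by default, feed independent. Operating profit is EBIT: product income
plus diversification income, minus purchased feed at the drawn feed price,
other variable costs, overheads, intervention cost deltas and straight-line
depreciation of intervention capex over a 10-year default life. The Monte
Carlo default is 10,000 iterations, seeded and bit-reproducible.

The hybrid carbon account applies to the 20-year mean net emission —
matching the net-zero definition — rather than year by year: tax = $80 ×
max(0, mean net), credit = $28 × max(0, −mean net). Tax and credit are
mutually exclusive and the post-account profit is continuous at net zero.
The tax exceeding the credit price encodes the policy intent that reaching
net-zero matters more than overshooting it.

Marginal abatement cost curves use pre-carbon-tax profits (the curves
describe intervention economics before any policy), order points by
ascending cost per Mg CO$_2$e, exclude zero-abatement scenarios and list
emission-increasing ones separately rather than plotting a negative
abatement.

## Impact score and sensitivity

Within a compared set, production and pre-tax profit are normalised by the
set maximum; net emissions are normalised by the set maximum and
inverse-coded. The total is the equally weighted sum in [0, 3]; exactly 3
requires being best in set on production and profit with zero mean net
emissions. Two interpretation choices were open and are resolved as
follows: the emissions component is clamped to [0, 1] so net-negative
scenarios cannot push the total beyond 3, and negative profits are floored
at zero before normalising (with a warning) since a negative normalised
bar has no meaning on this scale. Normalisation is per compared set — a
figure panel's worth of scenarios — not a global constant.

The sensitivity engine re-runs the full pipeline over a grid of inhibition
fractions (within [0.10, 0.99]) and tree perturbations (within ±20%) under
a shared seed, so climate and production are identical across grid points;
net emissions are then strictly decreasing along the inhibition axis and
exactly linear along the tree axis. `find_net_zero_area()` solves the tree
area that zeroes the 20-year mean by bisection; the non-tree annual series
is computed once from a full run and candidate areas are evaluated against
it (exact, because removals are linear in area and nothing else depends on
it), then the solution is verified end to end.

## Numerical choices and problem sizes

All randomness flows through explicit integer seeds; sub-stage seeds are
derived arithmetically from the run seed and stay far below 2$^{31}$.
Moisture deficits are clamped to their admissible interval; the temperature
modifier raises a domain error at or below −18.27 °C; pools are checked
non-negative after every step. The test suite runs the turnover model for
5,000 months against its closed-form fixed point (0.1% agreement), 10,000
randomised conservation steps (10$^{-9}$ relative), a 50,000-draw copula
check (correlation within 0.02), and 10,000-iteration Monte Carlo runs;
full-pipeline property tests use 26-year runs with reduced Monte Carlo
sizes, which changes nothing about the deterministic emission accounting
they assert.

## Known limitations

The production generator has no animal reproduction calendar, wool-quality
modelling, pasture species dynamics or irrigation scheduling; supplement
feeding is a single balance rule. Soil erosion, pH and nutrient limitation
are outside the turnover model; layers do not mix. Tree profiles are
illustrative. Emission factors are national-inventory-style defaults, not
farm measurements. Return-on-capital, discounting and land-price dynamics
are out of scope. Results should be read as internally consistent scenario
comparisons, not predictions for any particular enterprise.
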