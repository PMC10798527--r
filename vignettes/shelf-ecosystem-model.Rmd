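---
title: "Methods: mass balance, network transpose, and upwelling-driven dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mass balance, network transpose, and upwelling-driven dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shelfweb)
```

`shelfweb` implements a complete end-to-end shelf ecosystem modelling
chain: static mass balance of a multi-group food web, its re-expression
as a donor-normalized energy-flow network with detritus and nutrient
pools, and a daily nitrogen-currency simulation on a five-box cross-shelf
physical scaffold forced by an upwelling index. This vignette documents
the model equations, the assumptions and defaults behind every tunable
parameter, the numerical choices, and the limits of what the synthetic
test conditions can show.

## 1. The static mass balance

Each living functional group $i$ satisfies

$$B_i \left(\tfrac{P}{B}\right)_i EE_i + I_i + BA_i
  = \sum_j B_j \left(\tfrac{C}{B}\right)_j D_{ij} + E_i + F_i ,$$

production used within the system on the left, losses to predation,
emigration and fishing on the right. Exactly one of $\{B_i, EE_i\}$ is
unknown per group. Because the equation is linear in the unknown
biomasses once known-biomass predation is moved to the constant side, all
unknown $B$'s come from one linear solve over the fixed-EE subset
(`solve()` on the dense system; condition numbers above $10^{12}$ raise a
non-identifiability error naming the coupled groups); the remaining EE
values follow by direct evaluation. EE outside $[0,1]$ is a diagnostic,
collected in the imbalance report — the standard remedy,
`rebalance_by_scaling()`, multiplies survey biomasses that are known to
be underestimates.

Two bookkeeping conventions are worth noting:

* **BA placement.** The accumulation term $BA$ is applied on the
  production side, as the equation is written above; a
  `ba_convention = "canonical"` switch treats it as a right-hand loss
  instead. With the default $BA = I = 0$ the two agree exactly.
* **Detritus EE.** Detritus pools are never balance constraints. Their
  EE is reported from the pool budget — consumption of the pool divided
  by its inflow (feces, senescence, discards) — purely as a diagnostic.
* **Fleets** are stored as groups with `category = "fleet"` and enter
  only through $F_i$ (landings + discards), never the predation sum.

## 2. The donor-normalized network

The balanced consumption matrix is transposed into
$A_{ji} = D_{ij} c_j / \sum_j D_{ij} c_j$ with $c_j = B_j (C/B)_j$: the
fraction of the *consumed* share of prey $i$ going to consumer $j$. The
expanded network then closes each living group's production budget over

* living consumers ($A_{ji}$ rescaled by the consumed share of
  production),
* landings (out of the system) and discards (to the fishery-offal pool),
* emigration (export, taken off the top — the split of unconsumed
  production between senescence and emigration is not otherwise
  determined, so emigration is removed before fate routing),
* senescence of the residual, routed per the group's fate-table row.

The senescence share is computed as the residual that closes the column
to exactly 1, so column conservation holds to machine precision rather
than to the tolerance of a reconstruction. Separately, each consumer's
intake is split into feces ($1 - AE$, routed per the feces fate row),
growth ($P/Q$ of intake), and excretion to the ammonium pool.

**Excretion closure.** We take growth $= (P/Q) \times$ intake, feces
$= (1 - AE) \times$ intake, and excretion $= (AE - P/Q) \times$ intake
(clipped at zero). This closes the intake budget exactly *and* makes the
static balance point a fixed point of the dynamics: at equilibrium intake
equals $B (C/B)$, so growth equals $B (P/B)$, which is precisely the
production the network allocates away. The superficially natural
alternative — excretion $= AE(1 - P/Q) \times$ intake with growth
$= AE \cdot P/Q \times$ intake — also closes the budget but puts growth
systematically below allocated production by the factor $AE$, so every
consumer would decay by construction and no equilibrium diagnostics could
ever pass. Since all $P/Q \le 0.35 < AE = 0.8$ in the reference
parameterization, the clip at zero is never active there.

## 3. Physical scaffold

Five boxes span the shelf: I (inner, vertically integrated), II/III
(middle, surface/sub-surface), IV/V (outer, surface/sub-surface), split
at the annual-mean mixed layer depth (15 m default). The default
geometry describes a generic several-hundred-kilometre upwelling shelf
(alongshore 830 km; inner/middle/outer widths 15/15/30 km; mean depths
50/150/500 m); all of it is a constructor argument because box areas are
domain-specific.

* **Advection.** A daily upwelling index $u$ (m² s⁻¹ per metre of
  coastline) drives a volume flux $Q = u \times$ alongshore length along
  the closed circuit ocean → V → III → I → II → IV → ocean; negative
  $u$ (downwelling) reverses every arrow. Continuity holds exactly at
  each box. The per-metre-coastline index must be scaled by the domain's
  alongshore length; that conversion is dimensional necessity.
* **Boundary conditions.** Nutrients enter with the inbound flux at
  monthly climatological boundary concentrations (deep boundary under
  upwelling, surface boundary under downwelling). Non-nutrient groups
  see *reflective* boundaries: inbound water mirrors the receiving box's
  own concentration (no net import, no dilution) while offshore outflow
  exports; the export ledger reports the net of the two. A `"closed"`
  mode shuts the non-nutrient boundary entirely — the mass-conservation
  property tests run in that mode.
* **Retention.** Each group's susceptibility to advection is
  $1 - \text{retention}$; nutrients always move, nekton (retention 1)
  never does.
* **Vertical mixing.** Fickian exchange across the mixed-layer base
  (II↔III, IV↔V) at a piston velocity (default 1 m d⁻¹) supplies
  sub-surface nitrate to the mid- and outer-shelf surface boxes. Without
  it the advective circuit is the only vertical pathway and the
  mid-shelf surface box is cut off from nitrate entirely, which produces
  an implausible near-zero new-production share there.
* **Sinking.** Pelagic detritus sinks from the surface boxes into the
  boxes beneath at a configured daily fraction (default 0.2 d⁻¹).

## 4. Daily dynamics in nitrogen currency

State is a concentration matrix (boxes × variables, mmol N m⁻³):
nitrate, ammonium, living groups, detritus pools. Wet weight converts to
nitrogen via a carbon fraction of wet weight (default 0.1 g C / g ww) and
Redfield C:N = 106:16; group-specific factors can be supplied by editing
the configuration. Full trophic interactions run in boxes I, II, IV;
boxes III and V host only phytoplankton senescence (default 0.05 d⁻¹ of
standing stock to pelagic detritus), detritus metabolism, and
nitrification.

Each day, per food-web box:

1. **Transport** (advection, boundary input, mixing, sinking).
2. **Uptake.** Producer demand is `uptake_surge` × their balanced daily
   production $B_p (P/B)_p / 365$, capped by the available nutrient mass.
   The ammonium share follows the weighting
   $w_{NH_4} = \pi \cdot NH_4 / (\pi \cdot NH_4 + NO_3)$ with preference
   $\pi = 2$ by default. Realized uptake is the producers' growth.
3. **Donor-controlled flows.** Every living group's daily production
   capacity $B_i (P/B)_i / 365$ flows along the expanded network:
   consumption, landings out, discards to offal, export, senescence to
   pools. Consumer growth is $P/Q$ of intake; feces and excretion are
   routed as above. Detritus pools are grazed at their balanced annual
   turnover (consumption/standing stock from the mass balance),
   converted to a daily rate.
4. **Recycling.** Pelagic detritus and egg pools remineralize to
   ammonium at the pelagic rate; benthic detritus and offal at the
   benthic rate; benthic detritus is additionally sequestered (removed).
5. **Nitrification** converts ammonium to nitrate in boxes III and V
   (default 0.1 d⁻¹).

**Why an uptake surge?** If the producers' maximum uptake equalled their
balanced production, producer biomass could never grow — uptake in would
always equal allocation out — and steady advective flushing would drain
the web from the bottom. A surge ratio above 1 (default 2) lets producer
biomass expand until nutrient supply, not the initial condition, limits
production; the whole web then re-equilibrates proportionally, because
consumer growth and losses both scale linearly with flow. The precise
production-transfer equations of the donor-controlled tradition are not
fully pinned down by the sources this design follows, so this minimal
rule is isolated in `run_simulation()` step 3 for replacement.

One consequence of shared nutrient limitation is worth stating plainly:
two producers with *different* P/B competing for one nutrient pool
undergo competitive exclusion under this rule (their log-biomasses are
scalar multiples of the same integral). The reference parameterization
gives both phytoplankton groups the same P/B, and the synthetic
generator does likewise.

**Numerics.** Forward Euler at $\Delta t$ = 1 day — the forcing's native
step; producer relaxation rates ($\approx 0.6$ d⁻¹ at P/B = 215 yr⁻¹)
stay well inside Euler's stability region. Negative states are clipped
to zero with both a count and the clipped mass recorded in the ledgers,
so the nitrogen budget
(initial + boundary input − export − sequestration − landings + clipped)
can be audited exactly; conservation tests demand closure to $10^{-9}$
relative with a closed boundary and to $10^{-6}$ over 1000 steps
end-to-end. Trajectories are stored as annual means (daily totals
optionally), uptake ledgers per box per year.

**Diagnostics.** The f-ratio is NO₃ uptake / (NO₃ + NH₄ uptake) over the
final simulated year (the averaging window is a package choice — zone
definitions: inner = box I, mid = II + III, outer = IV + V); total
primary production is the volume-weighted mean daily uptake over the same
window. Extinction flags fire when a group's total mass falls below 1%
of its initial value at any time (production and biomass are
proportional for consumers under fixed P/B, so biomass is the tracked
quantity). `stability_metric()` compares the annual mean at the start
and end of the final 20-year window, with zero-reference groups reported
extinct rather than divided.

## 5. Tuning detritus recycling

`tuning_grid()` enumerates the three recycling parameters (pelagic
remineralization, benthic remineralization, benthic sequestration) over
$\{0, 0.1, \ldots, 1\}^3$ — 1331 cells in deterministic lexicographic
order. `run_grid()` runs a 20-year simulation per cell (per-cell
failures are recorded, not fatal; a `subsample` argument supports
desk-scale sweeps). `select_parameters()` scores zero-extinction cells
by the squared distance of each zone's f-ratio from the nearest point of
the target band (default 0.3–0.8) plus the squared relative deviation of
total primary production from the benchmark, equally weighted — the
qualitative selection rule made explicit — and breaks ties toward the
lexicographically smallest triple.

## 6. Input-preparation estimators

* **Delta-lognormal mean** (`delta_lognormal_mean()`): Pennington's
  minimum-variance unbiased estimator
  $(m/n)\,e^{\bar y}\,G_m(s^2/2)$ for zero-inflated lognormal catches,
  with the $G_m$ series truncated when terms fall below $10^{-12}$
  relative; $m = 0$ gives 0 and $m = 1$ gives $x_1/n$. The arithmetic
  mean is kept for acoustic-trawl-style data.
* **Conversions**: counts × ($a L^b$) length–weight biomass; volumetric
  to areal by the occupied depth range; gelatinous water-content scaling
  $(1 - wc_{gel})/(1 - wc_{ref})$ with visible defaults (0.96 gelatinous,
  0.80 crustacean, 0.75 fish water content — assumptions, not
  measurements); periodic linear interpolation for seasonal observations;
  satellite production to biomass by dividing the productive-season
  (April–September) wet-weight production rate by phytoplankton P/B.
* **Size partition**: $P_{small} = 0.30821\,\mathrm{Chl}^{-0.82351}$
  exceeds 1 below roughly 0.24 mg m⁻³ and is clamped to $[0, 1]$,
  since a fraction must be proper.
* **Subregional pipeline** (`subregional_biomass()`): per-group estimator
  → vertical integration → catchability scaler → average across
  spatially overlapping surveys → sum species into functional groups.
  Unmapped species are dropped with a warning, never silently.
* **Diet compilation**: unidentified material is removed before
  normalization; weight-based and frequency-of-occurrence proportions
  are treated as the same semantic after normalization (the sources mix
  them without a conversion); sources merge by predator sample size;
  species combine by biomass share; broad prey labels split across
  member groups in proportion to biomass, restricted to members observed
  in that predator's diet; `rescale_prey()` pins one prey and
  renormalizes the others proportionally; legacy averaging is an
  unweighted renormalized mean applied at the functional-group level.
* **Landings reallocation**: latitude-overlap fractions × cross-shelf
  occurrence proportions × gear-to-fleet mapping, with discards from
  per-fleet-per-group rates; total landed weight is conserved whenever
  the model bins cover the source zones.

## 7. What the synthetic data do and do not show

`make_toy_web()` builds webs *flow-first*: target EE values are chosen
inside $(0,1)$, the consumed share of each group's production is
allocated among next-layer consumers with log-uniform weights, and the
diet matrix is derived from the flows. Diet-first construction routinely
produces EE > 1 — the very problem mass-balancing exists to fix — so
flow-first construction is what guarantees balanceable test webs with
known answers. Consumer biomasses follow from intake and C/B, spreading
several orders of magnitude at 90 groups; top predators reach their EE
through fleet landings (10% discarded); AE is 0.8 for all consumers.

The generators reproduce the *statistical shape* of real inputs —
magnitude spans, zero-inflated lognormal catches, Dirichlet-perturbed
diets with sample sizes, seasonal upwelling with a summer maximum —
but not the taxon-specific structure of a real shelf: no
ontogenetic stages, no spatial patchiness beyond the box structure, no
gear selectivity. Passing tests on these webs demonstrates that the
algorithms are correct and the coupled system is stable under realistic
forcing statistics; it does not validate any particular ecosystem's
parameter values. The bundled 90-group parameter table supports the
static screens (biomass span, rate orderings, efficiency bounds,
biomass–trophic-level slope) but not a full dynamic reconstruction,
which additionally needs the deposited diet matrix, fate table, catch
tables, and observed forcing series.

Default study conditions used by the tests and the acceptance script:
synthetic upwelling with annual mean 0.5 m² s⁻¹, amplitude 1 (winter
downwelling), noise 0.1; boundary climatology 30/20 mmol m⁻³ NO₃ and
2/1 mmol m⁻³ NH₄ (deep/surface); 150-year stability runs under the
noise-free seasonal cycle; 20-year tuning runs; survey recovery at
1000 hauls × 500 replicates. Desk-scale property sweeps use 3–12-group
webs so the whole suite runs in well under a minute of simulation time.

## 8. Known limitations

* The dynamic production-transfer rule is a minimal donor-controlled
  closure, not a reproduction of any specific published integrator;
  predator functional responses, migration phenology, age structure, and
  linked life stages are out of scope.
* Producer dynamics equilibrate to nutrient supply; the balanced
  biomasses are initial conditions, not attractors, so long-run
  equilibria need not coincide with the static parameterization.
* The 2-D cross-shelf structure has no alongshore resolution; the
  15-subregion bookkeeping applies to input preparation, not to the
  dynamic simulation.
* Egg pools and fishery offal are recycled with the detritus rate
  constants of their layer (pelagic and benthic respectively); they have
  no rates of their own in the reference table.
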