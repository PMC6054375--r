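---
title: "Methods: an end-to-end box-model ecosystem simulator with scenario and bio-economic evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: an end-to-end box-model ecosystem simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`baltisim` couples a nitrogen-currency biogeochemical box model, an
age-structured trophic model and a fleet-level bio-economic model into one
offline-linked chain: synthetic physics forcing drives the ecosystem
simulation; terminal-state biomass indices from scenario comparisons scale
the stocks of the economic model. This vignette documents the governing
equations, the parameters that matter, the synthetic-data design, the
numerical choices and the known limitations.

## Spatial structure and state

The domain is a set of polygonal boxes connected by faces, with a shared
vertical layer scheme truncated per box at its maximum depth and one 0.5 m
sediment layer. Two geometries ship with the package: `baltic29` (29 boxes —
26 dynamic, 3 boundary — 100 faces, eight water layers with bounds at
5, 10, 30, 40, 50, 100, 200 and 450 m), a structural exemplar of a full
basin-scale domain whose polygon shapes are schematic; and `mini8`
(8 boxes, 1 boundary, 3 layers), the reduced whole-basin geometry on which
the shipped experiments run. Boundary boxes carry prescribed tracer
climatologies and receive no internal updates; they stand in for the
exchange with the open sea.

Water-column state is a per-box, per-layer concentration field over ten
tracers: nitrate, ammonium, silicate, oxygen, dissolved organic nitrogen,
labile and refractory detritus, and the three transported biota (small and
large phytoplankton, mesozooplankton), in mg N m^-3 (oxygen in mg O2 m^-3).
Sediment pools (nitrate, ammonium, labile and refractory detritus) are
total mass per box. Biomass is reported in metric tons wet weight through a
single declared conversion (2.5e7 mg N per ton); all internal accounting is
in mg N, which is what makes exact conservation checkable.

## Transport

Advection is first-order upwind donor-cell exchange by prescribed signed
face volumes at 12-hour resolution. The synthetic forcing is projected to
zero net volume flux per dynamic box and layer (rigid-lid box volumes), so
a spatially uniform tracer field is an exact fixed point and total tracer
mass over dynamic boxes changes only through boundary faces. Vertical
mixing is explicit diffusion, `rate * interface_area / interface_distance`,
sub-stepped for stability; settling moves detritus and large phytoplankton
downward and into the sediment; a linear bioturbation coefficient exchanges
dissolved nitrogen between the deepest layer and sediment porewater.
Operator order is fixed: advect, then mix, then settle, then sediment
exchange, twice daily. Because each operator is linear in the tracer field
and the forcing year repeats, the run loop precompiles them once into
per-step update matrices; the exported operator functions implement the
identical update rules and are what the oracle tests exercise.

Higher-order advection schemes were deliberately rejected: at box scale the
testable contracts are positivity, exact conservation and the documented
CFL bound (donor volume per 12 h), not dispersion accuracy.

## Biogeochemistry

Primary production follows
`growth = mu_max * min(N/(K_N + N), I/(K_I + I)) * B`
with a Liebig minimum of Michaelis–Menten nutrient and light terms —
combination rule chosen here; ammonium is drawn down before nitrate
(strict sequential preference, the simplest form consistent with common
practice in nitrogen-cycle box models of this family). Light is surface irradiance attenuated as
`I(z) = I0 exp(-integral(k_w + k_bio B))`, evaluated at layer mid-depth.
Oxygen is produced at the Redfieldian 15.14 mg O2 per mg N.

Detritus decays to ammonium at `lambda_L = 0.03 d^-1` (labile) and
`lambda_R = 0.003 d^-1` (refractory), DON at 0.01 d^-1, consuming oxygen
stoichiometrically with a floor at zero (anaerobic remineralization is
implicit). Nitrification (0.05 d^-1 above 500 mg O2 m^-3) recycles ammonium
to nitrate at 4.57 mg O2 per mg N. The nitrogen sinks are sediment burial
(1.2e-3 d^-1 of both sediment detritus pools, a design choice where the
split is unspecified) and denitrification: first-order loss (0.06 d^-1) of
sediment nitrate gated on bottom-water oxygen below 4000 mg O2 m^-3 —
a declared stand-in for a full diagenetic formulation. Surface oxygen
relaxes to a brackish-water saturation value at 0.3 d^-1; the air–sea
boundary condition is our choice, as box models of this type rarely state
one. Silica is a passive diatom-coupled tracer.

Every source and sink posts to a ledger (rivers, deposition, boundary
exchange, denitrification, burial, catch). The identity
`delta N = rivers + deposition + boundary - denitrification - burial - catch`
holds to machine precision at every daily step, and a fully closed system
(no sources, no boundary faces, F = 0) conserves total nitrogen exactly.
The catch term is our addition: fishery removals export nitrogen and a
budget without them cannot close.

## Trophic dynamics

Consumers use a shared-saturation, multi-prey modified Holling type II
response: intake of prey j per unit predator biomass is
`C a_j rho_j / (1 + (C/g) sum_k a_k rho_k)` per day — clearance-limited at
low prey density, capped at the maximum ration `g` at high density.
Effective prey density composes availability `a`, spatial overlap via the
distribution maps, a gape window on the prey:predator weight ratio (pools
use nominal individual sizes), and habitat-cover-weighted refuge. Pool
groups (mesozooplankton, benthic deposit feeders, a Nephrops-type
detritivore) feed in a fixed documented order; demands are capped at
available prey so mass balance is exact. Assimilated intake becomes growth;
the remainder splits 50/50 between egestion (labile detritus) and excretion
(ammonium).

Vertebrates (a sprat-like planktivore with 5 cohorts, a cod-like
bentho-piscivore with 10) carry numbers and structural/reserve weights per
cohort. Stage-level feeding uses biomass-weighted cohort parameters, scaled
by a condition factor (reserve:structural ratio relative to its reference,
clamped to [0.5, 1.5]). Growth increments reserve and structural weight
equally, capped at 1.5x the reference weight-at-age (excess is respired);
under starvation, reserves pay the basal metabolic cost (8e-4 d^-1) down to
a floor. Mortality is Baranov-partitioned between natural deaths (to labile
detritus where the stage lives) and fishery catch (to the catch ledger),
with F uniform in space and split juvenile/adult. Cannibalism operates
whenever the availability matrix allows it.

Recruitment is Beverton–Holt, `R = phi * alpha * S / (beta + S)`, with the
spawning stock ogive-weighted and `phi` the product of piecewise-linear
0-to-1 ramps in temperature, salinity and oxygen. The ramps are evaluated
**per spawning box** and habitat-weighted afterwards — reproductive-volume
logic: for the cod-like group (salinity ramp 10–12 psu, oxygen ramp
anchored at the 2 mL L^-1 equivalent, 2858–4287 mg O2 m^-3) only the
deep saline basin qualifies, so `alpha` is sized against that realized
`phi` (about 0.16 on the shipped geometry). Recruit biomass (egg-scale
individuals, 10 and 150 mg N) is debited from spawner reserves so the
nitrogen budget closes; piecewise-linear ramps were chosen over logistic
forms for testability. Ageing shifts cohorts annually into a terminal
plus-group; quarterly redistribution replaces spatial shares with the
quarter's map, restricted to boxes whose oxygen admits the group — if no
admissible box remains the group stage is lost to the sediment carrion
pool (an extreme-hypoxia rule that the shipped configuration never
triggers).

## Synthetic forcing and initial conditions

The generator produces one 12-hour-resolution calendar year, reused for
every projection year (exact annual periodicity). Temperature is an annual
sinusoid with coastal amplitude exceeding offshore (coastal winter minima
clamp at 0 degC); salinity declines monotonically along the entrance axis
with a positive depth gradient. Exchange volumes are per-face seasonal
sinusoids with seeded lognormal noise, winter-amplified, with faces
touching boundary boxes amplified 1.5x (episodic inflow events), then
projected divergence-free by a graph-Laplacian solve with the boundary
boxes as ground. The projection has a structural consequence worth knowing:
deep-layer circulation requires a loop in the deep-face graph, which is why
`mini8` gives its boundary box two deep faces — one deep basin is
ventilated by winter inflows (seasonal near-anoxia with re-oxygenation),
while the terminal deep basin is a stagnant cul-de-sac (permanent anoxia),
the two regimes observed in stratified brackish basins.

River loads are annual totals distributed over coastal boxes by area with
seeded variation, applied daily at even rates after coastal retention
(0.30), DIN/DON fractionation (0.70/0.30) and DON bioavailability (0.5) —
shipped defaults standing in for regionally estimated factors; the
non-bioavailable DON share enters refractory detritus so nitrogen is
conserved. A 0.3 share of each coastal load spills to the deepest adjacent
offshore box. The domain total (6e5 t N yr^-1) and the uniform atmospheric
deposition (0.15 mmol NH4 m^-2 day^-1) are basin-scale magnitudes.
Initial conditions are winter nutrient fields, plankton seeds normalized to
group targets, benthos allocated by habitat affinity, vertebrate numbers
from survivorship at the configured mortality, and quarterly maps from
seeded area-weighted allocations. Water-column detritus is purposefully
initialized very low (a tenth of the plankton standing stock) to avoid
spurious early grazing; sediment pools are seeded at typical standing
areal densities so the slow sediment inventory does not dominate spin-up.

What the generator does **not** emulate: real hydrographic events
(inflows are a seasonal statistical pattern, not a time series), horizontal
resolution below box scale, phosphorus limitation and cyanobacteria
dynamics, and the observational noise structure of survey data. Tests that
pass on this forcing therefore demonstrate the internal consistency and
qualitative response structure of the framework, not predictive skill for
any real year.

## Calibration of the shipped configuration

The reduced food web (two producers, mesozooplankton, two benthic pools,
two fish groups) was calibrated in the usual way for this model family:
rates were started from field-plausible magnitudes (clearance from specific
ration targets, P/B-consistent mortalities) and adjusted until the 60-year
run satisfied the standard criteria — a balanced equilibrium (drift below
2% per decade in annual-mean biomass, our operationalization of an
"equilibrium reached" statement), terminal biomass within 0.5x–2x of the
initial fields for at least 90% of groups, strictly decreasing cohort
numbers, spatial persistence, and an ecologically sound emergent diet.
Initial-condition targets were then set near the model's own attractor, as
one would initialize from a spun-up state. Structural stabilizers found
necessary during calibration, all standard devices: quadratic closure
mortality on mesozooplankton and the benthic pools (unresolved predation),
density-dependent bloom mortality on the large producer (aggregation
sinking), cod cannibalism, a benthos diet share for the adult predator
(buffering its response to prey-fish swings), and a gape floor that shelters
the first sprat cohort, whose early spawning contribution keeps recruitment
alive under heavy predation — the reduced web's analogue of the size
refuges, alternative prey and cannibalism that stabilize the full system. The large producer is deliberately ungrazed and
nutrient/settling-controlled while the small producer is grazer-controlled:
a classic coexistence split that keeps the bottom-up response to nutrient
load unambiguous.

## Scenario engine and terminal metrics

Scenarios hold per-box load multipliers and per-group F overrides
(juvenile defaulting to half the adult value), switched on instantaneously
at year 35 of a 60-year horizon; scenario and baseline share the forcing
seed so differences are attributable to the intervention alone. The
shipped catalog follows the ten printed experiment settings, including the
two "increase" scenarios whose catalog F values (0.64, 0.14) are double
rather than 1.5x the baselines — the printed values are used verbatim, and
on reduced geometries catalog boxes absent from the geometry are dropped.
Comparisons use arithmetic means over the terminal five years (window 1
recovers a final-year variant), percent change against baseline with
undefined flags for zero baselines, and stock-area indices in two variants
(plain box sums, and quarter-weighted by the distribution maps; they agree
exactly for quarter-invariant maps).

## Bio-economics

Stocks are held constant over the 2012–2037 projection; the ecosystem
signal enters as relative biomass indices scaling TSB. Catch production is
Cobb–Douglas in normalized form, `A (E/E_ref)^alpha (B/B_ref)^beta` with
intercepts in tons and both elasticities defaulting to 1. Quota caps are
`quota_share * TAC` per fleet and stock; when one binds, the fleet's effort
is scaled by the single factor that brings the choke stock exactly to
quota. Accounting is exact by construction: revenue minus fuel, variable,
crew-share, fixed and capital costs equals profit, split over areas by
activity keys. The behavior module is a bounded profit-following rule
(`E' = E (1 + 0.1 sign(profit) min(|profit|/revenue, 0.5))`), our minimal
interpretation of an adaptive-effort module; the discount rate defaults to
4% yr^-1 (config-exposed, as no printed value exists). The shipped fleet
catalog (three trawler length classes and a netter segment) and stock
table are plausible 2012-style magnitudes, labelled synthetic: absolute
NPV levels are configuration-dependent and only comparative statements
(scenario versus status quo) are meaningful.

## Numerical choices and problem sizes

Ecology runs on a daily explicit Euler step with capped transfers (no
state can go negative); physics on the 12-hour forcing cadence with CFL
asserted at operator construction; vertical diffusion sub-steps to a 0.4
stability fraction. The shipped experiments use the `mini8` geometry with
60-year horizons (the conservation test runs 10 years closed), sizes at
which the full test suite and the acceptance script each complete in
roughly 15–20 minutes on one core. Determinism is exact: a fixed seed
reproduces every trajectory bit-for-bit.

## Known limitations

One nutrient currency (no phosphorus, no cyanobacteria nitrogen fixation);
forced vertebrate distributions (no movement model); no egg/larval stages;
a single stock per species; fishing uniform in space with no seasonality;
boundary climatology rather than observed exchange; the economic module's
behavior rule is deliberately minimal. The `baltic29` geometry reproduces
counts and connectivity, not true polygon shapes, and is shipped for
structural tests rather than calibrated runs.

A known gap in the shipped calibration: deep bottom oxygen stays at or
above roughly 3 g O2 m^-3 year-round, i.e. the model is hypoxic enough to
gate denitrification and compress demersal habitat (the mechanism behind
the fishing-scenario responses) but never reaches the periodic full anoxia
of strongly stratified basins. Configurations that forced deep anoxia —
lower or per-box vertical mixing, faster sediment remineralization —
destabilized the planktivore through the same habitat-compression
mechanism, so the calibrated equilibrium was preferred. Per-box mixing
overrides are exposed in `transport_params()` for users who want to explore
that regime.
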