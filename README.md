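# baltisim

`baltisim` is a desk-scale, spatially explicit end-to-end ecosystem simulator
for Baltic-type brackish seas, with a scenario engine for nutrient-load and
fishing-pressure experiments and a downstream multi-fleet bio-economic
evaluation. It is aimed at researchers who want a fully testable,
self-contained box-model analogue of large end-to-end frameworks: every
process — nitrogen biogeochemistry, tracer transport, age-structured trophic
dynamics, management scenarios, fleet economics — is implemented in R with
exact mass accounting, and all inputs can be generated synthetically.

## The model in brief

The domain is a set of polygonal boxes with a shared vertical layer scheme
(truncated per box at its depth) plus one sediment layer; boundary boxes
carry prescribed tracers. Nitrogen is the model currency; oxygen and silica
are tracked alongside.

* **Transport.** First-order upwind donor-cell advection by prescribed,
  divergence-free face exchange volumes at 12-hour resolution; diffusive
  vertical mixing (with per-box overrides); particle settling of detritus
  and large phytoplankton into the sediment; linear sediment–water solute
  exchange.
* **Biogeochemistry.** Primary production with a Liebig minimum of
  Michaelis–Menten nutrient and light limitation
  (`mu_max * min(N/(K_N+N), I/(K_I+I))`, ammonium before nitrate);
  remineralization of labile/refractory detritus and DON; nitrification;
  oxygen production, sediment oxygen demand and air–sea relaxation;
  oxygen-gated sediment denitrification and detritus burial as the nitrogen
  sinks.
* **Trophic dynamics.** Biomass-pool invertebrates and age-structured fish
  with a shared-saturation modified Holling type II functional response
  `C a_j rho_j / (1 + (C/g) * sum_k a_k rho_k)`, availability, gape windows,
  habitat refuge and forced quarterly distribution maps; assimilation-based
  growth with exact intake = growth + detritus + NH4 accounting; Baranov
  catch partitioning; Beverton–Holt recruitment `R = phi * alpha*S/(beta+S)`
  with piecewise-linear temperature, salinity and oxygen ramps evaluated per
  spawning box (reproductive-volume logic).
* **Scenarios.** A ten-scenario catalog (status quo, four river
  nitrogen-load reductions, five fishing-mortality changes), 60-year runs
  with a 35-year spin-up, instantaneous forcing change, five-year terminal
  averages and percent-change comparisons with migration-aware stock
  indices.
* **Economics.** A multi-fleet, multi-stock evaluation: Cobb–Douglas catch
  production against fixed base-year references, TAC quota shares with a
  single-factor choke rule, effort-behavior adjustment, per-line cost
  accounting and NPV over 2012–2037.

A nitrogen budget ledger (rivers, deposition, boundary exchange,
denitrification, burial, catch) closes to machine precision at every daily
step; a closed system conserves total nitrogen exactly.

## Worked example

```r
library(baltisim)

g  <- example_geometry("mini8")        # reduced whole-basin test geometry
sc <- build_scenarios(g)

base <- run_projection(g, scenario = sc$status_quo, seed = 1)
scn5 <- run_projection(g, scenario = sc$scenario5,  seed = 1)  # pan-Baltic -33% N

cmp <- compare(scn5, base)
subset(cmp$groups, group %in% c("PS", "NE", "FSR", "FCD"))
#>     group baseline scenario pct_change undefined
#> PS     PS  6490687  5726328    -11.776     FALSE
#> NE     NE    56009    43395    -22.520     FALSE
#> FSR   FSR  1574140  1083653    -31.159     FALSE
#> FCD   FCD   211730   196057     -7.402     FALSE

round(cmp$bottom_o2$delta[2:5], 1)     # bottom-O2 gain in the loaded boxes
#> [1] 102.0 209.9 205.7 218.0
```

The percent changes are terminal five-year average biomass changes against
the baseline: a pan-Baltic 33% nutrient-load reduction propagates bottom-up
(small phytoplankton −11.8%, the Nephrops-type detritivore −22.5%, the
planktivorous fish −31.2%, the predator fish only −7.4%) while bottom
oxygen in the treated coastal boxes improves by 100–220 mg O2 m⁻³ — the
response attenuates at the top of the food web.

Calibration diagnostics for any run:

```r
rep <- calibration_report(base)
rep$biomass
#>   group initial terminal factor flagged
#> 1    PS 6400000  6490687  1.014   FALSE
#> 2    PL  500000   438380  0.877   FALSE
#> 3    ZM 2500000  2312952  0.925   FALSE
#> 4    BD 5300000  5128076  0.968   FALSE
#> 5    NE   56000    56009  1.000   FALSE
#> 6   FSR 1500000  1574140  1.049   FALSE
#> 7   FCD  200000   211730  1.059   FALSE
```

Every group ends within the 0.5–2x band of its initial field, reaches
equilibrium (drift below 2% per decade) and keeps a strictly decreasing age
structure; the predator's emergent diet is split between the prey fish and
benthos, never read from configuration (`diet_composition(base, "FCD_adult")`).

Feeding the scenario's stock indices into the bio-economic layer:

```r
stocks <- scale_stocks(default_stocks(), cmp)
project_npv(default_fleets(), default_stocks())$npv_total   # 50.9 (million EUR)
project_npv(default_fleets(), stocks)$npv_total             # 13.3
```

The nutrient-reduction scenario lowers the fishery's net present value, the
comparative contract of the economic chain (absolute EUR levels are
synthetic configuration).

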