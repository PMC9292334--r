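# mnrecycle

Micronutrient recycling by marine microzooplankton: a mixed-layer box model
with climate scenarios, a fixed-food-quality counterfactual, and a
variance-attribution pipeline for the drivers of recycling.

## What it is for

Zooplankton grazing returns a large share of the scarce trace metals — Fe,
Zn, Cu, Co and Mn — to the dissolved pool of the surface ocean. The rate of
this recycling, and its metal:carbon ratio (the *recycling stoichiometry*),
are controlled by four drivers: the stoichiometric match between grazer and
diet (**food quality**, FQ = (M:C)<sub>zoo</sub> / (M:C)<sub>prey</sub>),
the preference-weighted metal content of the prey field (**prey
quantity**, Σᵢ P<sub>ij</sub>·pᵢ), **sea surface temperature**, and
**zooplankton biomass**. `mnrecycle` is for modellers and biogeochemists
who want a desk-scale, fully testable version of this system:

* an NPZD-style box model with Droop-type variable phytoplankton metal
  quotas (maximum quotas 80, 40/123, 16, 1.2 and 8 ×10⁻⁶ mol:mol for Fe,
  Zn (nano/diatom), Cu, Co, Mn), fixed zooplankton stoichiometry, and an
  assimilation efficiency AE(FQ) = ae_max·min(FQ, 1/FQ)^ae_shape that
  peaks for balanced diets;
* preindustrial-control vs. warming/stratification scenario pairs on an
  1801–2100 calendar, with decadal analysis windows and a counterfactual
  that freezes food quality at its preindustrial climatology;
* attribution of recycling variance by ordinary least squares
  (response = α·FQ + β·preyQ + γ·SST + δ·zooB + ε) and the LMG
  relative-importance decomposition of R², with a >50 % explained-variance
  filter and ternary dominance classification;
* a synthetic panel generator with *analytic* population importance
  shares, so every statistical stage is validated against closed-form
  truth.

## Worked example

```r
library(mnrecycle)

## 20 years of mixed-layer dynamics under constant forcing
params <- ecosystem_params()
traj <- run_simulation(params, t_end = 20 * MN_YEAR_DAYS)
signif(budget_check(traj), 3)
#>        C       Fe       Zn       Cu       Co       Mn
#> 1.75e-13 1.93e-14 1.04e-12 2.84e-13 5.06e-13 5.86e-13

signif(unlist(tail(traj$diag[, c("npp", "recycle_c", "fq.Fe",
                                 "recycle_stoich.Fe")], 1)), 4)
#>               npp         recycle_c             fq.Fe recycle_stoich.Fe
#>         2.064e-03         9.915e-04         3.412e-01         3.797e-05
```

The budget check says every element's inventory change matches the
integrated source/mixing/export fluxes to ~10⁻¹³ relative — the ecosystem
terms cancel exactly. At equilibrium the box fixes ~2.1 mmol C m⁻³ d⁻¹,
recycles ~1.0 mmol C m⁻³ d⁻¹ through microzooplankton, and the Fe food
quality of 0.34 (metal-rich diet) yields an Fe recycling stoichiometry of
38 µmol Fe : mol C.

```r
## attribution against known ground truth
gp <- generate_driver_panel(panel_spec(
  n = 5000, coefficients = c(fq = 1, prey_q = -0.5, sst = 0.3, zoo_b = 0.8),
  target_r2 = 0.7, seed = 42))
lmg_shares(gp$panel)
#> <mn_importance> R^2 = 0.7088
#>      fq  prey_q     sst   zoo_b
#> 0.35970 0.08775 0.03034 0.23100

signif(gp$truth$shares, 4)       # analytic population shares
#>      fq  prey_q     sst   zoo_b
#> 0.35350 0.08838 0.03182 0.22630
```

The empirical LMG shares (fractions of total response variance; they sum
to R²) match the analytic population shares of the generating process to
well under ±0.01. `classify_dominance()` labels this panel food-quality
dominated and `ternary_coordinates()` places it at (0.30, 0.29) in the
ternary plane used for regional dominance maps.

Scenario experiments follow the same pattern:

```r
pair <- run_pair(params, scenario_spec())     # control + RCP-style ramp
cf   <- fixed_fq_counterfactual(pair)         # food quality frozen at PI
```

## Command line

A thin CLI over the same functions ships in `inst/cli/`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","mnrecycle.R",package="mnrecycle"))')" \
    check            # closed-box budget + LMG oracle self-test
# subcommands: simulate | scenario | counterfactual | attribute | synth | check
```

Every run writes deterministic CSV (12 significant digits) plus a JSON
manifest with seeds and file checksums.

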