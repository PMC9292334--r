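---
title: "Micronutrient recycling by zooplankton: model, scenarios and driver attribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Micronutrient recycling by zooplankton}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mnrecycle)
```

## The problem

Trace metals — iron, zinc, copper, cobalt and manganese — are essential
micronutrients for marine plankton, present at nano- to picomolar levels in
surface waters. A large part of their upper-ocean supply is internal:
microzooplankton graze on phytoplankton and organic particles, assimilate
part of the ingested metal, and excrete the remainder in dissolved form.
This *recycling flux*, and its metal:carbon ratio (the *recycling
stoichiometry*), respond to four drivers: the stoichiometric match between
grazers and their diet (*food quality*), the metal available in the prey
field (*prey quantity*), water temperature, and zooplankton biomass.

`mnrecycle` implements a desk-scale version of this system: a
zero-dimensional mixed-layer ecosystem model that produces self-consistent
time series of recycling fluxes and all four drivers, scenario machinery for
warming/stratification experiments and a fixed-food-quality counterfactual,
and a variance-attribution pipeline (ordinary least squares plus the LMG
decomposition of R²) that quantifies each driver's contribution.

## The box model

### Pools and currencies

The model tracks, in a single well-mixed surface box exchanging with a deep
reservoir:

* `n` — dissolved macronutrient. Plankton C:N:P is fixed, so the
  macronutrient is carried in carbon-equivalent units (mol C m⁻³) and one
  currency serves for all organic carbon accounting.
* `d.<El>` — dissolved metal for each of Fe, Zn, Cu, Co, Mn (mol m⁻³).
* `pc.<group>`, `pm.<group>.<El>` — carbon and internal metal content of two
  phytoplankton groups (nanophytoplankton, diatoms).
* `zc` — microzooplankton carbon. The zooplankton metal pool is implicit,
  `zc × q_zoo`, because the zooplankton metal:C stoichiometry is fixed.
* `poc`, `pom.<El>` — particulate organic carbon and particulate metal.

Quotas are absolute mol metal per mol C throughout (e.g. the maximum Fe
quota is `80e-6`); no display scalings enter the computational core. The
model calendar uses 360-day years (twelve 30-day months), which makes
monthly sampling and decadal windows exact.

### Phytoplankton: Droop quotas

Growth is the minimum of macronutrient Michaelis–Menten limitation and a
Droop-type Fe limitation, times a Q10 temperature factor
(`q10^((T−20)/10)`, Q10 = 1.88):

```
mu = mu_max * Tf * min(n / (n + k_n), (q_Fe − q_min) / (q_max − q_min))
```

Only the Fe quota limits growth; the other metals are tracked but
non-limiting. Metal uptake is quota-regulated,

```
v = v_max * d / (d + k_up) * (1 − q / q_max),
```

so quota dynamics follow `dq/dt = v − mu·q`: when carbon growth slows,
quotas accumulate toward their maxima — the luxury-accumulation behaviour
that makes prey stoichiometry respond to nutrient stress. The maximum
quotas (Fe 80, Zn 40/123 for nano/diatoms, Cu 16, Co 1.2, Mn 8, all ×10⁻⁶
mol:mol) and the fixed zooplankton quotas (Fe, Zn, Cu 10×10⁻⁶; Co
0.16×10⁻⁶; Mn 1×10⁻⁶) follow the observational synthesis used by the
global model family this box model distils.

### Grazing and the zooplankton budget

Microzooplankton graze on three prey — nanophytoplankton, diatoms and
particles — with a shared-saturation response and fixed preferences
(1, 0.5, 0.3):

```
g_i = g_max * Tf * zc * p_i F_i / (k_g + sum_j p_j F_j)
```

Food quality for each metal is the zooplankton quota divided by the
grazing-weighted diet quota, `FQ = q_zoo / (M:C)_diet`; `FQ = 1` is a
stoichiometrically balanced diet. Assimilation efficiency declines
symmetrically (in log space) as the diet departs from balance:

```
AE(FQ) = ae_max * min(FQ, 1/FQ)^ae_shape
```

The ingested-metal budget then assimilates
`min(AE(FQ)·I_m, demand)` with `demand = ae_c · I_c · q_zoo` — the metal
needed to build new zooplankton biomass at the fixed body stoichiometry —
and splits the unassimilated remainder `sigma_diss : (1 − sigma_diss)`
between dissolved excretion (the recycling flux) and particulate egestion.

**Why `ae_shape = 2`.** With a linear decline (`ae_shape = 1`) the
assimilation capacity on the metal-rich side is
`ae_max · FQ · I_m = ae_max · q_zoo · I_c`, which is proportional to the
demand `ae_c · q_zoo · I_c` and exceeds it whenever `ae_max > ae_c`. The
demand cap then always binds, and food quality can never influence
recycling for FQ < 1 — contradicting the qualitative behaviour the model is
meant to express (recycling increases as assimilation efficiency drops). A
quadratic decline keeps the AE limit active on both sides of FQ = 1, so the
food-quality mechanism operates throughout. The exponent is a parameter
(`ae_shape`), isolated in one operation, and can be set to any value
including 0 (AE independent of food quality), which the counterfactual
isolation test exploits.

**Fixed body stoichiometry and the shortfall ladder.** Zooplankton carbon
growth is never metal-limited here; to keep the body quota exactly fixed
when assimilation falls short of demand, the shortfall is drawn first from
the dissolved-excretion term (floored at zero), then from the egestion
term, then from the ambient dissolved pool (a small dissolved-absorption
flux). The *diagnostic* recycling flux is the gross excretion
`sigma_diss · (I_m − assimilated)` — the quantity that responds to food
quality — while the net pool fluxes (after the ladder) are what the ODE
integrates, so mass is conserved exactly. Reporting the net flux instead
would let the quota-maintenance draw cancel or even invert the
assimilation-efficiency signal.

### Closure and particles

Zooplankton losses use a quadratic closure `m_z · Tf · zc²`, scaled by the
same Q10 factor as the other metabolic rates. The temperature scaling
matters structurally: with an unscaled closure, equilibrium zooplankton
biomass inherits the grazing Q10 and becomes perfectly collinear with
temperature, which would make temperature and biomass statistically
inseparable in any attribution. Particles remineralize (`lambda_rem`) back
to the dissolved pools and sink out of the box (`lambda_sink`); the box
exchanges with fixed deep reservoirs at rate `kappa(t)` and receives
constant external sources.

### Integration and budget closure

The coupled ODEs are integrated with fixed-step RK4, default `dt = 0.25` d.
All biological sink terms vanish smoothly as their source pool empties
(Michaelis–Menten and proportional closures), so positivity is inherent;
round-off undershoots below 10⁻¹⁴ are clipped and anything larger raises an
error naming the pool and time. Boundary fluxes (sources, deep exchange,
export) are accumulated as auxiliary state *by the same RK4 pass*, so
`budget_check()` compares two independently coded accountings of the same
mass: a 100-year closed box conserves every element to ~10⁻¹⁵ relative, and
open runs close their source/export budgets to ~10⁻¹² (the package demands
10⁻⁸ and 10⁻⁶).

The right-hand side is only piecewise smooth (Liebig minima, the quota-cap
clamp, the assimilation `min`). The integrator's fourth-order convergence
is therefore verified on a configuration whose trajectory stays clear of
those switching surfaces (uptake slowed so no quota reaches its cap);
across regime switches the formal order degrades locally, as it must for
any non-smoothed model.

### Default parameters

Rates are per day, concentrations mol m⁻³, referenced to a ~100 m mixed
layer at 20 °C: `mu_max` 1.2/1.5 (nano/diatom), `k_n` equivalent to ~0.1/1
µM N, `g_max` 3 with `k_g` 0.02 mol C m⁻³, carbon gross growth efficiency
`ae_c` 0.3, `sigma_diss` 0.5 (the dissolved/particulate split of
unassimilated material is genuinely unconstrained; 0.5 treats both pathways
symmetrically), `m_z` 20 (mol C m⁻³)⁻¹ d⁻¹, `m_p` 0.05, sinking 0.1
(≈10 m d⁻¹ over 100 m), remineralization 0.05, deep exchange `kappa0`
0.02 d⁻¹. Deep metal reservoirs are set to typical deep-ocean
concentrations (e.g. 0.8 nM Fe, 6 nM Zn) and external sources to small
constant values. Metal uptake capacity defaults to `q_max` per day, and
the Droop floor `fe_q_min` is 4×10⁻⁶ mol:mol (5 % of the Fe maximum) —
a floor is required for Fe limitation to operate at all, and its value
mainly sets how sharp the limitation onset is. At these defaults the box
equilibrates with diatoms dominating the phytoplankton (the classic
competitive-exclusion outcome of a single limiting currency and one shared
grazer); the nanophytoplankton pool persists only in transients and under
time-dependent forcing.

## Scenarios and the counterfactual

A scenario pairs a constant-forcing control with a climate run that ramps
temperature up by `delta_t` (default +4 °C) and deep exchange down by the
fraction `delta_kappa` (default 0.4, the stratification proxy) from the
branch year to the end of the run. Model year *y* maps to calendar year
1800 + *y*; runs span 1801–2100, branch in 1851, and are analysed over
PRESENT (1991–2000), FUTURE (2091–2100) and the preindustrial reference
PI_REF (1801–1900). The climate run branches from the control state, so the
two trajectories are bitwise identical before the ramp.

`fixed_fq_counterfactual()` repeats the climate run with the per-element
food quality *inside the assimilation-efficiency term* frozen to its PI_REF
climatology from the control run; biomass, prey quantity and temperature
evolve freely. With `ae_shape = 0` the counterfactual is bitwise identical
to the climate run, which verifies that the freeze touches nothing else.

**The food-quality drift experiment.** In this box model the default
warming/stratification ramp *lowers* phytoplankton quotas (faster growth
dilutes quotas; reduced mixing cuts the metal supply), which moves Fe food
quality from ≈0.36 toward 1 — the recycling-damping direction. To exercise
the amplifying direction, the drift experiment raises the zooplankton Fe
quota to 50×10⁻⁶ so the preindustrial diet is already metal-poor
(FQ ≈ 1.66, inside the regime where the AE limit rather than the demand cap
bounds assimilation). The same quota decline then pushes FQ monotonically
away from 1 (to ≈1.94 by 2100), assimilation efficiency falls, and the
reference run recycles relatively more Fe than the frozen-FQ run in every
post-branch year; by the FUTURE window the normalized recycling
stoichiometry gap is ≈0.10.

## Driver attribution

For any panel of samples the two response kinds — recycling flux and
recycling stoichiometry — are regressed on the four drivers with an
ordinary least-squares Gaussian model (identity link):

```
response = alpha·fq + beta·prey_q + gamma·sst + delta·zoo_b + intercept + error
```

A large error variance flags drivers missing from the model. The fraction
of response variance credited to each driver uses the LMG decomposition:
the average, over all orderings in which a predictor can enter the model,
of its sequential increase in R². It is computed through the equivalent
subset-weighted form

```
share_j = sum over S ⊆ others of  |S|!·(p−1−|S|)!/p! · (R²(S ∪ {j}) − R²(S))
```

with all subset R² values obtained from the sample covariance matrix.
Shares are non-negative, invariant to affine rescaling of any column, and
sum exactly to the full-model R² — they are fractions of total variance,
not of explained variance. An independent oracle
(`lmg_shares_bruteforce()`) enumerates all 24 orderings explicitly and
agrees with the subset form to 10⁻¹²; for orthogonal designs the shares
reduce to squared simple correlations.

Grouped attribution (`attribute_by_group()`) fits each
region × element × response-kind × period group separately, reports failed
groups (e.g. a zero-variance regressor in a degenerate region) with their
reason rather than dropping them, and flags groups whose R² does not exceed
0.5 as excluded from ternary output. The three biotic shares (quality,
quantity, biomass) are renormalized to the 2-simplex for ternary plotting —
quality at (0,0), quantity at (1,0), biomass at the apex — while the
temperature share is carried separately as an absolute fraction of
variance. Dominance ties break in the fixed order quality > quantity >
biomass and are flagged.

## Synthetic panels and what the tests show

`generate_driver_panel()` draws predictors as multivariate normals per
region (optionally AR(1)-autocorrelated in time, since monthly geophysical
series are autocorrelated), builds the response as a known linear
combination plus Gaussian noise scaled to a target population R², and
returns the analytic truth: population subset-R² values computed from the
generating covariance, pushed through the same LMG weights
(`population_shares()`). Recovery checks fit 50 panels of n = 20 000 at
population R² = 0.6 and require coefficients within 3 standard errors and
shares within ±0.02 of the analytic values.

The generator emulates the *statistical* structure the attribution stage
assumes — linear response, Gaussian noise, region blocks, temporal
autocorrelation — and deliberately not the features that make real fields
hard: nonlinear driver interactions, spatial covariance, non-Gaussian
tails, observation error. Passing recovery tests therefore demonstrates
that the decomposition machinery is correct, not that a linear model is
adequate for any particular ocean field; the simulator-backed panels probe
the latter within this model's own dynamics.

## The constructed-variance experiments

Validating attribution end-to-end needs ensembles where the "right answer"
is known. This is less innocent than it sounds: in a tightly coupled
ecosystem at equilibrium, every driver is a monotone function of the same
grazing-pressure scalar, so an ensemble that varies any one parameter
leaves all four drivers almost perfectly collinear and the LMG split
becomes an uninformative ~equal division. Naive "vary only zooplankton
parameters" sweeps in this model yield prey quantity or food quality as the
top-ranked driver of their own recycling response.

`dominance_experiment()` therefore breaks the collinearity deliberately:

* **Biomass (`"zoo_b"`).** A weak-grazing-coupling regime (high background
  phytoplankton mortality, strongly buffered dissolved pools) in which
  grazing is a minor prey loss term, with members spread in initial
  zooplankton biomass and in the closure coefficient, sampled over a
  30-day window. The prey field cannot respond on that horizon, so the
  biomass spread keeps its variance to itself; the biomass share is the
  largest for all five metals.
* **Temperature (`"sst"`).** Members differ in mean temperature and share
  a 20-day "weather-band" sinusoid. The Q10-scaled closure makes
  equilibrium biomass temperature-independent, and the biological pools
  cannot track the weather band (their relaxation times are comparable to
  or longer than the period), so temperature retains unique, in-phase
  variance through its instantaneous effect on grazing and recycling
  rates; the temperature share is the largest for all five metals.

Both designs are fixed, seeded and cheap (tens of model-years), and both
hold across independent Latin-hypercube seeds.

## Numerical conventions and degenerate inputs

* Recycling stoichiometry with a zero carbon flux returns a `NaN` sentinel,
  never an error, so time series keep their alignment.
* Core stoichiometric operators reject non-positive inputs (an empty or
  metal-free diet is a caller error); the simulator intercepts the
  degenerate cases (zero grazing steps skip the budget).
* Zero-variance regressors abort a fit with the column named; grouped
  attribution converts that into a reported per-group failure.
* CSV output is written at 12 significant digits, making identical
  configuration + seed runs byte-identical.
* All randomness (panel generation, Latin hypercubes) is seed-controlled;
  the simulator itself is deterministic.

## Problem sizes used in the checks

The shipped verification uses 100-year budget runs at `dt = 0.25` d,
300-year scenario triplets for the counterfactual, ensembles of 6–8
members over 2–6 model years for the dominance experiments, 100 random
panels for the oracle equivalence, and 50 synthetic replicates of
n = 20 000 for statistical recovery — sizes chosen so the full suite
re-runs in a couple of minutes on one core while leaving each estimate's
sampling error well below the tolerance it is compared against.

## Limitations

This is a process model of mechanisms, not a representation of geography:
no spatial grid, no seasonal light cycle, no mesozooplankton, no ligand
chemistry or scavenging, no oxygen-dependent sediment sources, and regional
structure only in the form of ensemble members or labelled panel blocks.
The assimilation-efficiency form is a stated stand-in with the qualitative
properties (peak at FQ = 1, symmetric log-space decline) isolated behind
one operation; the multi-prey grazing response and closure are standard
NPZD choices rather than a transcription of any particular global model's
supplement. Competitive exclusion at constant forcing leaves one
phytoplankton group dominant at equilibrium. Statistical attribution treats
panel rows as exchangeable; the AR(1) generator exists precisely so users
can quantify what autocorrelation does to those fits.
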