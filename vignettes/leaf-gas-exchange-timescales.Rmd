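---
title: "Separating timescales in optimality-based leaf gas exchange"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating timescales in optimality-based leaf gas exchange}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leaflapse)
```

## The problem

Eco-evolutionary optimality (EEO) theory predicts the leaf trait
combinations that maximize carbon gain net of resource costs, and those
predictions — the optimal c~i~:c~a~ ratio χ, coordinated V~cmax~ and J~max~,
an acclimated stomatal conductance — have proven remarkably good at the
week-to-month scale. But a leaf hit by a sudden environmental change is not
at that optimum: c~i~ re-equilibrates in seconds, stomatal aperture in
minutes, biochemistry over weeks, and the anatomical maximum conductance
g~smax~ only as new leaves develop. `leaflapse` makes that temporal
separation explicit. A perturbation in ambient CO~2~ or vapour pressure
deficit (VPD) is replayed through five states, and the leaf's position is
tracked on two ratio axes: (c~i~:c~a~)/χ (how far the interior is from its
slow setpoint) and g~s~:g~smax~ (how far aperture is from its anatomical
ceiling, whose conservative operating point is γ ≈ 0.25).

## Model components and assumptions

**Photosynthesis (FvCB).** `net_assimilation()` takes the minimum of the
Rubisco-limited and RuBP-regeneration-limited rates; ties are labelled
`"rubisco"` so output is deterministic. Temperature responses of Γ\*, K~c~
and K~o~ are Bernacchi-style Arrhenius functions around 25 °C references
expressed as partial pressures (4.332, 39.97 and 27480 Pa) that scale
linearly with total pressure; O~2~ partial pressure is 0.2095 P~atm~. Leaf
temperature equals air temperature (no energy balance), mesophyll
conductance is not represented, and triose-phosphate limitation is omitted
as negligible at the conditions simulated. Dark respiration is excluded by
default (`rd_frac = 0`); the scenario time-lapses track gross assimilation.

**The coupled c~i~ solver.** `solve_ci()` intersects the demand curve with
the supply line A = (g~s~/1.6)(c~a~ − c~i~)/P~atm~; conductances are stored
and reported for water vapour throughout, and the 1.6 diffusivity ratio
converts to CO~2~ inside the supply term. Demand is monotone increasing and
supply monotone decreasing in c~i~, so the root on [Γ\*, c~a~] is unique;
bracketed root finding (tolerance near machine precision, residual checked
against 10^-8^ µmol m^-2^ s^-1^) cannot miss it. The *engine* couples the
supply line to the RuBP-regeneration branch rather than the full minimum:
around the coordinated state the two branches cross exactly at the setpoint,
and the simulated trajectories (including the small assimilation responses
to stomatal adjustment below the setpoint) are those of the light-limited
branch. The full minimum remains available via `demand = "min"`.

**Least-cost χ.** `chi_optimal()` implements
χ = Γ\*/c~a~ + (1 − Γ\*/c~a~) ξ/(ξ + √D) with
ξ = √(β(K + Γ\*)/(1.6 η\*)), VPD in Pa and η\* the water viscosity relative
to 25 °C (Vogel correlation; exactly 1 at the 25 °C used by the bundled
scenarios, so the correlation choice does not touch the reference numbers).
β defaults to 146. Under the reference temperate conditions (25 °C, 1 kPa,
400 ppm, sea-level pressure) this gives χ = 0.753, falling to 0.687 at
2 kPa (−8.8 %) and to 0.738 at 800 ppm (−2.0 %).

**Coordinated biochemistry.** `acclimated_state()` sets J~max~ where the
marginal carbon return on electron-transport capacity equals its maintenance
cost c against the light-response curvature θ (defaults c = 0.05336251,
θ = 0.85), giving the co-limited assimilation A = φ~0~ I m ω\*/(2θ), and
sets V~cmax~ = A/m~C~ so both FvCB branches meet exactly at c~i~ = χ c~a~.
This electron-transport-cost formulation was chosen over the simpler
√(1 − (c\*/m)^2/3^) correction because only the former reproduces the
magnitude of V~cmax~ acclimation the framework is meant to exhibit
(−23 % for a CO~2~ doubling, +3.6 % for a VPD doubling; the simpler form
gives −15 % and +1 %).

**Instantaneous stomata.** `instantaneous_gs()` maximizes
A(g~s~) − λ g~s~ D/P~atm~ at frozen V~cmax~ and J~max~: a Cowan–Farquhar
optimum with a constant marginal water price λ. The objective is concave
(concave increasing gain, linear cost) and is maximized by deterministic
golden-section search (tolerance 10^-10^), verified in tests against a
dense grid oracle to better than 0.1 %. If the optimum exceeds g~smax~ the
engine clips it and flags `functional_control_exceeded` (configurable via
`clip_gs`).

## Tunable parameters

| constant | default | units | role |
|---|---|---|---|
| `beta` | 146 | – | carboxylation:transpiration unit-cost ratio in ξ |
| `phi0` | 0.035 | mol CO₂ mol⁻¹ photons | intrinsic quantum yield (absorptance folded in) |
| `theta_j` | 0.85 | – | curvature of the J light response |
| `c_jmax` | 0.05336251 | – | marginal maintenance cost of J~max~ |
| `lambda_water` | 4.5105e-4 | mol CO₂ (mol H₂O)⁻¹ | marginal water price of the minute-scale optimum |
| `gamma_ratio` | 0.25 | – | operational g~s~:g~smax~ setpoint |
| `rd_frac` | 0 | – | dark respiration as a fraction of V~cmax~ |

Two of these are calibrated rather than taken from first principles, and the
calibration targets are part of the model definition. φ~0~ is pinned so
that the reference temperate growth state assimilates 13.9 µmol m^-2^ s^-1^
(which simultaneously puts the acclimated conductance at 0.226 mol m^-2^
s^-1^, consistent with the operational values the framework assumes).
λ is pinned so that the minute-scale stomatal closure after a CO~2~
doubling at fixed biochemistry is 23.5 %; with that single constant the
package also reproduces the accompanying relaxation of (c~i~:c~a~)/χ
(−5.4 %) and the ~1 % assimilation dip at that step. The same λ predicts a
10.9 % minute-scale closure when VPD doubles. A weaker reported VPD response
(≈7 %) would require a scenario-dependent water price (the two scenarios
invert to λ of 4.51 and 4.09 × 10⁻⁴ respectively); we prefer the single
constant and document the discrepancy as a model limitation rather than
switching cost functions between scenarios.

## Scenario semantics and numerical choices

`run_scenario(env0, env1)` enforces that only c~a~ and/or VPD change
(temperature and light perturbations have no calibrated pathway here and are
rejected). The five states are computed as:

0. `initial_state(env0)` — fully acclimated; ratio_ci = 1, ratio_gs = γ.
1. *seconds* — all traits frozen; c~i~ re-solved. χ is re-evaluated at the
   new environment immediately (it is a prediction, not a leaf property), so
   the ratio axis moves both through c~i~ and through its denominator.
2. *minutes* — `instantaneous_gs()` at frozen biochemistry, clipped at
   g~smax~; c~i~ re-solved.
3. *weeks* — V~cmax~ re-coordinates to `env1`; g~s~ moves to sustain
   c~i~ = χ c~a~ by diffusion. By default J~max~ keeps its initial value:
   the framework's idealized time-lapses track V~cmax~ only, and freezing
   J~max~ yields the characteristic small assimilation declines at steps
   1→2→3 (−1.0 %, −1.6 % in the CO~2~ scenario) with the assimilation
   maximum at the instantaneous step. With `jmax_acclimate = TRUE`
   electron-transport capacity re-optimizes as well, and step 4 then equals
   `initial_state(env1)` in every field (a property the test suite checks at
   relative 10^-4^ over randomized perturbations). Under the frozen-J~max~
   default the two ratio axes still land exactly on 1 and γ, but g~s~,
   J~max~ and A~leaf~ retain a 1–4 % memory of the pre-perturbation
   electron-transport capacity.
4. *seasonal and longer* — g~smax~ ← g~s~/γ; only the anatomical ceiling
   moves.

Normalization divides each trait's five-step series by its own maximum
within the scenario (per trait, per scenario), giving series on [0, 1] with
maximum exactly 1. Percent changes are computed on full-precision values;
rounding happens only at display.

One known asymmetry follows from the constant λ: because the instantaneous
water price is below the long-run marginal cost implicit in the acclimated
state, the minute-scale optimum of an *unperturbed* leaf sits ~25 % above
its setpoint. A null perturbation therefore shows a transient g~s~ excursion
at step 2 before the week-scale step restores the setpoint; all other traits
and all later steps are exact fixed points. Calibrating λ at the current
acclimated state would remove the excursion but would roughly double the
minute-scale responses, contradicting the behaviour the framework is built
to exhibit.

## The trait catalog

`load_trait_catalog()` ships 17 reviewed leaf traits spanning stomata and
hydraulics (g~s~, operational g~s~, g~smax~, c~i~, Ψ~leaf~, K~leaf~,
hydraulic capacity, vein density), photosynthetic biochemistry (V~cmax~,
J~max~, photosynthetic pathway, light-saturated capacity) and
morphology/lifespan (LMA, LD, LVA, LL, genome size), each with response
mechanisms (physiological / phenotypic / evolutionary, possibly several)
and a timescale band from seconds to millions of years. Bands map to
log~10~-second midpoints (minutes → 1.8, weeks → 5.8, ...) so that
`traits_responsive_within(elapsed)` reduces to arithmetic and is provably
monotone in elapsed time. The catalog is a plain CSV with a schema-versioned
header; a corrected or extended table can be supplied without code changes.

## What the scenarios do and do not show

The bundled scenarios are idealized step experiments at 25 °C and constant
light: they demonstrate the ordering and rough magnitude of responses, not
diurnal dynamics, soil-moisture feedbacks, temperature acclimation, canopy
gradients or whole-plant hydraulics. Continuous-time behaviour between the
five states is intentionally absent — the framework is state-to-state. The
test suite runs both scenarios end to end plus randomized perturbation
property checks (a few hundred assertions, seconds of runtime); the grid
oracles for the solver and optimizer use 2–40 × 10^4^ evaluation points,
sizes chosen to make discretization error negligible relative to the
tolerances being asserted.

## Session info

```{r}
sessionInfo()
```
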