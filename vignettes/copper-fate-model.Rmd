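---
title: "Modelling the fate of copper added to lakes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the fate of copper added to lakes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cufate)
```

## The question

When dissolved copper enters a lake — an algaecide dose, a spill, an
experimental spike — it does not degrade, but it is *removed*: copper
binds strongly to suspended particles, settles to the sediment, and is
sequestered there, under anoxic conditions as highly insoluble copper
sulfide. For hazard assessment the operative questions are *how fast*
the water column clears (half-time and 70 % removal time, judged
against a 28-d convention) and *how permanent* the sediment sink is
(can diffusion, resuspension or re-oxidation return copper to the
water?). `cufate` implements a three-layer toolkit for those questions:
a closed-form settling framework, a two-compartment lake simulator with
simplified speciation, and a fitting pipeline for observed
concentration series.

## The settling-removal framework

For a well-mixed water column of depth $H$ (m) holding suspended
particulate matter (SPM) at concentration $m$ (mg/L) that settles with
velocity $v_s$ (m/d), total metal partitioned with a distribution
coefficient $K_D$ (L/kg) is lost to the bed at the first-order rate

$$k \;=\; \frac{S\,K_D}{H\,(1 + K_D m)}, \qquad S = v_s\,m ,$$

with the limits $k \to v_s/H$ when $K_D m \gg 1$ (all metal rides the
particles) and $k \to v_s m K_D / H$ when $K_D m \ll 1$. Removal times
follow as $t_x = \ln(100/x)/k$, $x$ the percentage *remaining* (50 for
the half-time, 30 for 70 % removal), so for any first-order process
$t_{70}/t_{50} = \ln(100/30)/\ln 2 \approx 1.737$ exactly. Washout
contributes $1/\tau$ ($\tau$ the hydraulic detention time);
`dilution_half_time()` gives the washout-only half-time
$\ln 2 \cdot \tau$ used to show flushing is far too slow to explain
observed clearances. Plotted against $H/S$, $t_x$ is a straight line
(`removal_time_curve()`), which is how disparate lakes, microcosms and
enclosures are compared on one axis.

```{r framework}
settling_loss_rate(3, 2.5, 15, 10^4.48)     # standardized lake, 1/d
removal_time(c(50, 30), 3, 2.5, 15, 10^4.48)
```

## The two-compartment simulator

`simulate_lake()` integrates total copper in a completely mixed oxic
water column over a single active sediment layer, per m^2 of lake bed:

* **water column**: loading (spike, scheduled re-doses, or continuous
  inflow at concentration $C_{in}$), settling of the particulate
  fraction, washout, diffusive exchange, resuspension input;
* **sediment layer**: settling input, diffusive exchange, resuspension
  loss, burial at the net solids accumulation rate
  $\max(0, v_s m - v_r \rho_s)$, which keeps the layer thickness
  constant;
* **partitioning**: re-equilibrated algebraically every step
  (instantaneous equilibrium; no sorption kinetics).

Numerics: fixed-step operator splitting with a Heun
(predictor–corrector) transport substep at `dt_d = 0.01` d, the
equilibrium re-solved at each stage. Steps that would drive a mass
negative are halved recursively; below $10^{-6}$ d the run aborts.
Halving the step changes reported concentrations by well under 0.5 %,
and with resuspension and diffusion disabled the simulator matches the
closed-form exponential to better than 0.5 % everywhere — both are
enforced by the test suite. Mass is conserved to round-off; the
`mass_balance()` ledger (pools normalized to an input of 100) must
close to 0.1.

### Speciation

Two partitioning modes stand behind the simulator
(`partitioning_model()`):

* **empirical**: constant $\log K_D$ = 4.48 (water) / 4.39 (sediment),
  field-derived review values.
* **isotherm** (the "calculated" mode): a Freundlich-type stand-in for
  a per-step speciation calculation,
  $\log K_D = \log K_{D,ref} + (n-1)\log_{10}(c/c_{ref})$, clamped to a
  calibrated band. A full humic-binding speciation engine is out of
  scope; the stand-in preserves the one property that matters to fate —
  $K_D$ rises as the dissolved concentration falls — and is fully
  testable. Calibration: the reference $\log K_D = 4.85$ is pinned at
  the initial dissolved concentration (17 µg/L) of the standardized
  35 µg/L spike, the low end of the band a speciation model predicts
  for that run; the band top 4.88 is the clamp; and the exponent
  $n = 0.964$ is taken from the second documented drift (a reservoir
  simulation in which $\log K_D$ rose 4.49 → 4.57 while the
  concentration fell about 2.2 decades: slope $\approx 0.08/2.2$).
  Ambient DOC above the 2 mg/L calibration value scales the
  operational $K_D$ by $(1 + K_{DOC}\cdot 2)/(1 + K_{DOC}\cdot DOC)$:
  copper held by (non-settling) dissolved organic matter lowers the
  effective particle affinity, so high-DOC waters clear more slowly.

Dissolved copper (operationally < 0.45 µm, so *including* Cu–DOC
complexes, which do not settle) is split by
$f_{DOC} = K_{DOC}\,DOC/(1 + K_{DOC}\,DOC)$ with the conditional
constant $K_{DOC} = 100$ L/mg chosen so that complexation exceeds 98 %
already at 2 mg/L DOC, as observed in typical natural waters; a simple
hydrolysis side-reaction coefficient ($pK = 6.5$) estimates the free
Cu²⁺ share of the inorganic remainder. A diagnostic
`hydroxide_saturation_index()` (default $pK_{sp} = 19.32$ for
Cu(OH)₂ — the controlling phase and constant are a documented
assumption) flags conditions where direct (hydr)oxide precipitation is
plausible; precipitation itself is not simulated in the water column.

In **anoxic** sediment, copper titrates the acid-volatile sulfide
(AVS) pool *before* any sorptive phase (copper outcompetes other trace
metals for sulfide): 1 mol Cu per mol AVS as CuS, or 2:1 as Cu₂S.
While capacity remains, porewater sits at a solubility-limited floor
(default 10⁻³ µg/L — copper sulfides are effectively insoluble), so
diffusion points *into* the bed. The AVS pool is fixed: no sulfide
regeneration or oxidation kinetics; redox state is a scenario switch.
Copper beyond the stoichiometric capacity partitions to the
sulfide-free sorptive phases (POC/HFO/HMO) — not to the empirical
anoxic $K_D$, which describes sulfide-bearing sediment and would
understate porewater copper exactly when the sulfide buffer is gone.
This is what lets a large spike over a low-AVS bed reverse the net
diffusive flux, the one condition under which the sediment leaks.

In **oxic** sediment there is no sulfide phase; particulate copper is
apportioned across particulate organic carbon, hydrous ferric oxide
and hydrous manganese oxide in proportion to phase content × phase
coefficient. The coefficients are calibrated constants, not
thermodynamic ones: at the base composition (5 % POC — the
standardized sediment organic-carbon content, an assumption —
18 600 mg/kg HFO, 154 mg/kg HMO) they reproduce a 95.34 / 4.3 / 0.36 %
split of particulate copper and an effective sulfide-free sorptive
$K_D$ of $10^{3.53}$ L/kg. The oxic preset uses the speciation-mode
model; under the much weaker sorption, porewater copper is higher and
the net diffusive flux points *out* of the bed, though it moves only a
few percent of the load over a year.

### Scenario defaults and their provenance

The standardized lake (`builtin_scenarios()$euses_base`) is a
generalized 3-m lake: $v_s$ = 2.5 m/d, $m$ = 15 mg/L, DOC = 2 mg/L,
pH 7.07/7.56 (water/sediment), hardness 516 mg/L CaCO₃, anoxic
sediment with AVS = 9.1 µmol/g, solids 500 g/L bulk, resuspension
2.44 cm/yr, and a 35 µg/L spike. Values not documented for the
standardized scenario are package assumptions, chosen once and exposed
as configuration knobs: depth 3 m (the regional-model standing-water
depth, and the value that makes the framework's removal times
internally consistent), no washout for spike scenarios (the reported
base-case removal times match settling-only kinetics), active sediment
depth 0.05 m, and a diffusive mass-transfer coefficient of 0.01 m/d
(the classic $D/\delta$ scale, ~10⁻⁹ m²/s across ~1 cm). Porosity
follows from bulk solids over a 2.6 kg/L grain density. The
flow-through enclosure preset uses its documented characteristics
(10 m deep, $v_s$ = 0.2 m/d, SPM 5.9 mg/L, 11.4 µg/L inflow) with two
assumptions: $\tau$ = 100 d, which with the documented loss rate
0.0091 d⁻¹ reproduces the observed ~6 µg/L steady state
$C_{in}/(1+k\tau)$, and $\log K_{D,w}$ = 5.15, back-calculated so the
settling framework yields that same rate.

## Fitting observed series

`fit_first_order()` estimates $k$ from $C = C_0 e^{-kt}$, by default as
OLS on $\ln C$ versus $t$ (the error model in field data is closer to
multiplicative, and the slope's t-interval gives an exact 95 % CI under
lognormal noise); Levenberg–Marquardt on the untransformed scale is
available since the choice is not documented for the original
analyses. Samples at/below detection are excluded, not substituted (no
substitution rule is documented). A fit is *unsupported* when the
interval for $k$ reaches zero — equivalently the slope's upper limit
indicates an increase — and `removal_summary()` then falls back to
interpolating the fraction-remaining curve, measured from the
*post-dose maximum* (accommodating delayed-mixing peaks), reporting
"not observed" when a threshold is never crossed. Interval propagation
is antitone: the lower time bound uses the upper rate bound. Duplicate
series are averaged arithmetically on their common grid before
fitting.

## Synthetic data: what it does and does not show

The generators (`generate_spike_series()`,
`generate_flowthrough_series()`, `generate_scenario_suite()`) emulate
the *statistical shape* of the field studies: spike decays with dense
early sampling (0–22 d), repeated dosing, and rise-to-steady-state
flow-through series sampled biweekly over 400 d, all with seeded
multiplicative lognormal noise (mean-1, default CV = 0.10 — no error
model is documented, and concentrations are positive with roughly
proportional errors). They make the pipeline testable end-to-end: exact
parameter recovery on noiseless input, ~95 % CI coverage over seeded
Monte-Carlo replicates, and fitted removal times that fall on the
$t_x$-versus-$H/S$ line. They do *not* emulate real-data pathologies —
irregular sampling gaps, detection-limit censoring patterns, storms and
resuspension events, non-first-order tails — so passing tests validate
the estimator machinery, not robustness to field mess.

## Problem sizes

Simulations in the tests and the reproduction script use the 0.01-d
step over 28-d (water column), 120-d (sensitivity suite) and 365-d
(sediment) horizons, 1000 Monte-Carlo replicates for CI coverage and
500 for rate recovery; each piece runs in seconds on one core.

## Known limitations

No vertical structure in either compartment (no stratification, no
sediment profiles or bioturbation mixing); no carbonate system,
competing metals, or temperature dependence; no water-column
precipitation (the saturation index is diagnostic only); AVS fixed, so
oxidative remobilization appears only through the oxic/anoxic scenario
switch; rivers and shallow direct-adsorption systems are out of scope.
The speciation stand-in is calibrated to two documented $K_D$ ranges
and should not be extrapolated to chemistries far from them.
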