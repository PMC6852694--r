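# cufate

Copper added to a lake does not degrade — it is *removed*: it binds to
suspended particles, settles, and is sequestered in the sediment, under
anoxic conditions as highly insoluble copper sulfide. For environmental
hazard assessment the questions are how fast the water column clears
(50 % and 70 % removal times, judged against a 28-day convention) and
how permanent the sediment sink is. `cufate` is an R package for
ecotoxicologists and fate modellers that answers both with three
connected layers:

1. **Closed-form settling framework.** For a well-mixed column of depth
   *H* with SPM concentration *m* settling at *v*<sub>s</sub> and a
   distribution coefficient *K*<sub>D</sub>, total metal is lost at

   *k* = *S K*<sub>D</sub> / (*H*(1 + *K*<sub>D</sub>*m*)),  *S* = *v*<sub>s</sub>*m*,

   with removal times *t*<sub>x</sub> = ln(100/*x*)/*k* (*x* =
   percentage remaining). Functions: `settling_loss_rate()`,
   `removal_time()`, `removal_time_curve()` (the *t*<sub>x</sub> vs
   *H*/*S* line), `dilution_half_time()`, `steady_state_continuous()`.

2. **Two-compartment simulator.** `simulate_lake()` integrates a mixed
   oxic water column over one active sediment layer (settling,
   resuspension, diffusive exchange, burial, washout; spike, re-dose or
   continuous loading) with partitioning re-equilibrated every step:
   constant empirical *K*<sub>D</sub> or a calibrated
   concentration-dependent isotherm, Cu–DOC complexation, AVS-limited
   sulfide precipitation in anoxic sediment, POC/HFO/HMO sorption in
   oxic sediment. `mass_balance()` returns the normalized flux ledger,
   `extract_removal_times()` the clearance times,
   `run_sensitivity_suite()` the standard parameter grid.

3. **Time-series pipeline.** `fit_first_order()` (log-linear OLS or
   nonlinear least squares) with 95 % CI propagation to removal times
   (`removal_times_from_fit()`), an interpolation fallback for series
   without first-order structure (`interpolate_removal_time()`), and
   `removal_summary()` for collections with duplicate averaging.
   Seeded synthetic generators (`generate_spike_series()`,
   `generate_flowthrough_series()`, `generate_scenario_suite()`) make
   everything testable without field data.

## Worked example

Simulate a 35 µg/L copper spike in the standardized 3-m lake
(*v*<sub>s</sub> = 2.5 m/d, SPM 15 mg/L, log *K*<sub>D,w</sub> = 4.48,
anoxic sediment with AVS = 9.1 µmol/g):

```r
library(cufate)
setup <- builtin_scenarios()$euses_base
sim <- simulate_lake(setup, duration_d = 28, dt_d = 0.01)
extract_removal_times(sim, phase = "dissolved")
#> <removal_times> [simulation]
#>   t50: 2.65 d
#>   t70: 4.62 d
```

Dissolved copper falls by half in ~2.7 d and by 70 % in ~4.7 d —
settling does in days what washout would need most of a year for
(`dilution_half_time(365)` ≈ 253 d). Over a full year the sediment is
where the copper ends up, and stays:

```r
mass_balance(simulate_lake(setup, duration_d = 365, dt_d = 0.01))
#> <mass_balance_ledger> (input normalized to 100 )
#>   remaining_water          0.4790
#>   in_sediment             93.8311
#>   buried                   5.6899
#>   exported                 0.0000
#>   gross_settling         144.9117
#>   gross_resuspension      46.6668
#>   net_diffusion            1.2761
#>   closure: 100.0000 (should equal 100 within 0.1)
```

More than 99 % of the dose sits in or below the active sediment layer;
the net diffusive flux (positive = into the bed) points downward
because sulfide precipitation keeps porewater copper near zero.
Sequestration is effectively irreversible — the one modelled exception
is a large spike over low-AVS sediment, which saturates the sulfide
pool and turns the diffusive flux outward.

The numbered scripts under `analysis/` walk the full study:
`01_removal_framework.R` (closed-form times per scenario),
`02_water_column.R` (empirical vs concentration-dependent
*K*<sub>D</sub>), `03_sensitivity.R`, `04_sediment.R` (anoxic/oxic/
AVS-exceeded ledgers), `05_timeseries_fits.R`, `06_removal_curve.R`
(*t*<sub>30</sub> vs *H*/*S*). Each writes its tables under `results/`
with a run manifest. The vignette (`vignettes/copper-fate-model.Rmd`)
documents the model, parameter provenance and design choices.

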