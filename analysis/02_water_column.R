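#!/usr/bin/env Rscript
# Water-column fate of a 35 ug/L copper spike in the standardized lake,
# simulated with the two-box model under the empirical and the
# concentration-dependent (speciation stand-in) distribution
# coefficients.

suppressMessages(library(cufate))
dir.create("results", showWarnings = FALSE)
catalog <- builtin_scenarios()

runs <- list(empirical = catalog$euses_base,
             calculated = catalog$euses_calculated)
for (nm in names(runs)) {
  sim <- simulate_lake(runs[[nm]], duration_d = 28, dt_d = 0.01,
                       record_dt_d = 0.1)
  rt <- extract_removal_times(sim, phase = "dissolved")
  out <- sprintf("results/02_timeseries_%s.csv", nm)
  write.csv(sim$series, out, row.names = FALSE)
  cat(sprintf("%-10s KD: t50 = %.2f d, t70 = %.2f d;", nm,
              rt$t50_d, rt$t70_d))
  cat(sprintf(" dissolved at 28 d = %.3g ug/L\n",
              tail(sim$series$cw_diss_ug_L, 1)))
  if (nm == "calculated") {
    cat(sprintf("  water-column log KD ranged %.3f-%.3f over the run\n",
                min(sim$series$log_kd_w, na.rm = TRUE),
                max(sim$series$log_kd_w, na.rm = TRUE)))
  }
  write_manifest(sprintf("results/02_manifest_%s.yml", nm),
                 step = "simulate", setup = runs[[nm]],
                 outputs = basename(out))
}
cat("Equilibrium particulate share: empirical",
    sprintf("%.1f%%;", 100 * particulate_fraction(10^4.48, 15)),
    "calculated (at dosing)",
    sprintf("%.1f%%\n", 100 * particulate_fraction(10^4.85, 15)))
cat("The stronger partitioning in the calculated mode removes copper",
    "faster.\n")
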