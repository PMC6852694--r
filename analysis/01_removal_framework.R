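#!/usr/bin/env Rscript
# Closed-form settling-removal framework applied to the built-in
# scenarios: loss rates, 50%/70% removal times, and the dilution-only
# half-times used to rule out washout as the dominant removal process.

suppressMessages(library(cufate))
dir.create("results", showWarnings = FALSE)

catalog <- builtin_scenarios()
rows <- lapply(names(catalog), function(nm) {
  sc <- catalog[[nm]]$scenario
  pm <- catalog[[nm]]$model
  kd <- if (pm$mode == "empirical") 10^pm$log_kd_water else
    isotherm_kd(pm$isotherm_ref_conc_ug_L, pm)
  k <- settling_loss_rate(sc$depth_m, sc$settling_velocity_m_d,
                          sc$spm_mg_L, kd)
  data.frame(scenario = nm,
             H_m = sc$depth_m,
             v_s_m_d = sc$settling_velocity_m_d,
             m_mg_L = sc$spm_mg_L,
             log_kd = round(log10(kd), 3),
             k_per_d = k,
             t50_d = log(2) / k,
             t70_d = log(100 / 30) / k)
})
tab <- do.call(rbind, rows)
write.csv(tab, "results/01_framework_removal_times.csv",
          row.names = FALSE)

cat("Settling-only removal times (closed form):\n")
print(tab, digits = 3, row.names = FALSE)

cat("\nDilution-only half-times for comparison:\n")
cat(sprintf("  detention 365 d   -> t50 = %.0f d\n",
            dilution_half_time(365)))
cat(sprintf("  detention 91.25 d -> t50 = %.1f d\n",
            dilution_half_time(91.25)))
cat("Both are far longer than the few-day settling half-times above:\n")
cat("washout is not the dominant removal process in these systems.\n")

write_manifest("results/01_manifest.yml", step = "removal-framework",
               outputs = "01_framework_removal_times.csv")
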