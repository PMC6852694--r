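test_that("a zero dose stays identically zero", {
  sim <- simulate_lake(lake_scenario(), metal_dose("spike", 0),
                       partitioning_model(), duration_d = 5, dt_d = 0.05)
  expect_true(all(sim$series$cw_total_ug_L == 0))
  expect_true(all(sim$series$sed_ug_m2 == 0))
})

test_that("with feedbacks off the simulator matches the analytic solution", {
  sc <- feedback_free_scenario()
  pm <- partitioning_model()
  sim <- simulate_lake(sc, metal_dose("spike", 35), pm,
                       duration_d = 20, dt_d = 0.01)
  k <- settling_loss_rate(sc$depth_m, sc$settling_velocity_m_d,
                          sc$spm_mg_L, 10^pm$log_kd_water)
  expected <- 35 * exp(-k * sim$series$time_d)
  rel <- abs(sim$series$cw_total_ug_L - expected) / expected
  expect_lt(max(rel), 0.005)

  # extracted removal times equal the closed forms ln2/k, ln(10/3)/k
  rt <- extract_removal_times(sim, "dissolved")
  expect_rel_equal(rt$t50_d, log(2) / k, rel = 0.005)
  expect_rel_equal(rt$t70_d, log(10 / 3) / k, rel = 0.005)
  expect_equal(rt$t70_d / rt$t50_d, log(100 / 30) / log(2),
               tolerance = 1e-3)
})

test_that("mass is conserved to 0.1% in spike, re-dose and continuous runs", {
  pm <- partitioning_model()
  runs <- list(
    spike = simulate_lake(lake_scenario(), metal_dose("spike", 35), pm,
                          duration_d = 60, dt_d = 0.02),
    redose = simulate_lake(
      lake_scenario(),
      metal_dose("spike", 250,
                 redose_schedule = data.frame(time_d = 20,
                                              conc_ug_L = 250)),
      pm, duration_d = 40, dt_d = 0.02),
    washout = simulate_lake(
      lake_scenario(hydraulic_residence_time_d = 40),
      metal_dose("spike", 35), pm, duration_d = 60, dt_d = 0.02),
    continuous = simulate_lake(builtin_scenarios()$melimex_continuous,
                               duration_d = 200, dt_d = 0.02)
  )
  for (nm in names(runs)) {
    mb <- mass_balance(runs[[nm]])
    expect_lt(abs(mb$closure - 100), 0.1, label = nm)
    expect_gte(mb$gross_settling, 0)
    expect_gte(mb$gross_resuspension, 0)
  }
})

test_that("halving the step changes reported concentrations by < 0.5%", {
  setup <- base_setup()
  a <- simulate_lake(setup, duration_d = 10, dt_d = 0.02,
                     record_dt_d = 0.5)
  b <- simulate_lake(setup, duration_d = 10, dt_d = 0.01,
                     record_dt_d = 0.5)
  rel <- abs(a$series$cw_total_ug_L / b$series$cw_total_ug_L - 1)
  expect_lt(max(rel, na.rm = TRUE), 0.005)
})

test_that("spiked water column declines monotonically without feedback", {
  sim <- simulate_lake(feedback_free_scenario(), metal_dose("spike", 35),
                       partitioning_model(), duration_d = 30, dt_d = 0.01)
  expect_true(all(diff(sim$series$cw_total_ug_L) <= 0))
  expect_true(all(sim$series$cw_diss_ug_L <=
                    sim$series$cw_total_ug_L + 1e-12))
  expect_true(all(sim$series$cw_total_ug_L >= 0))
})

test_that("re-dose events add mass instantaneously at the scheduled time", {
  dose <- metal_dose("spike", 250,
                     redose_schedule = data.frame(time_d = 20,
                                                  conc_ug_L = 250))
  sim <- simulate_lake(lake_scenario(), dose, partitioning_model(),
                       duration_d = 40, dt_d = 0.01, record_dt_d = 0.1)
  s <- sim$series
  before <- s$cw_total_ug_L[max(which(s$time_d < 20))]
  at <- s$cw_total_ug_L[min(which(s$time_d >= 20))]
  expect_equal(at - before, 250, tolerance = 250 * 0.02)
})

test_that("continuous loading approaches the closed-form steady state", {
  sc <- feedback_free_scenario(depth_m = 10, spm_mg_L = 5.9,
                               settling_velocity_m_d = 0.2,
                               hydraulic_residence_time_d = 100)
  pm <- partitioning_model(log_kd_water = 5.15)
  k <- settling_loss_rate(10, 0.2, 5.9, 10^5.15)
  k_eff <- k + 1 / 100
  sim <- simulate_lake(sc, metal_dose("continuous",
                                      inflow_conc_ug_L = 11.4),
                       pm, duration_d = ceiling(10 / k_eff), dt_d = 0.02)
  c_ss <- steady_state_continuous(11.4, 100, k)
  expect_rel_equal(utils::tail(sim$series$cw_total_ug_L, 1), c_ss,
                   rel = 0.02)
})

test_that("anoxic and oxic runs move diffusion in opposite directions", {
  cat <- builtin_scenarios()
  anoxic <- mass_balance(simulate_lake(cat$euses_base,
                                       duration_d = 365, dt_d = 0.02))
  oxic <- mass_balance(simulate_lake(cat$euses_oxic,
                                     duration_d = 365, dt_d = 0.02))
  expect_gt(anoxic$net_diffusion, 0)      # into the sediment
  expect_lt(oxic$net_diffusion, 0)        # out of the sediment
  expect_lt(abs(oxic$net_diffusion), 5)   # a small share of the load
})

test_that("sediment sulfide never exceeds the cumulative AVS capacity", {
  setup <- builtin_scenarios()$euses_low_avs
  setup$dose <- metal_dose("spike", 1000)
  sim <- simulate_lake(setup, duration_d = 365, dt_d = 0.02)
  sc <- setup$scenario
  cap_ug <- sc$avs_umol_g * 1e-6 * 1000 * sc$sediment_solids_g_Lbulk *
    sc$sediment_depth_m * 63.546 * 1e6
  sulf <- sim$series$frac_sulfide * sim$series$sed_ug_m2
  expect_true(all(sulf[is.finite(sulf)] <= cap_ug * (1 + 1e-9)))
  # the capacity binds in this run and diffusion reverses direction
  expect_gt(max(sulf, na.rm = TRUE), cap_ug * 0.999)
  expect_lt(mass_balance(sim)$net_diffusion, 0)
})

test_that("the sensitivity suite behaves as the standardized grid should", {
  suite <- run_sensitivity_suite(duration_d = 120, dt_d = 0.02)
  expect_true(all(c("base", "slow_settling", "high_doc",
                    "loading_1000_ug_L") %in% suite$variant))
  imax <- which.max(suite$t70_d)
  expect_identical(suite$variant[imax], "slow_settling")
  others <- suite[suite$variant != "slow_settling", ]
  expect_true(all(others$attained_70_within_28d))
})

test_that("higher DOC slows calculated-mode removal", {
  cat <- builtin_scenarios()
  lo <- extract_removal_times(
    simulate_lake(cat$euses_calculated, duration_d = 28, dt_d = 0.02),
    "dissolved")
  hi <- extract_removal_times(
    simulate_lake(cat$euses_high_doc, duration_d = 28, dt_d = 0.02),
    "dissolved")
  expect_gt(hi$t70_d, lo$t70_d)
})

test_that("removal-time extraction flags thresholds never reached", {
  sc <- feedback_free_scenario(settling_velocity_m_d = 0.001)
  sim <- simulate_lake(sc, metal_dose("spike", 35),
                       partitioning_model(), duration_d = 5, dt_d = 0.05)
  rt <- extract_removal_times(sim)
  expect_true(is.na(rt$t50_d))
  expect_match(rt$note, "not observed")
  expect_error(
    extract_removal_times(
      simulate_lake(builtin_scenarios()$melimex_continuous,
                    duration_d = 5, dt_d = 0.05)),
    "spike")
})
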