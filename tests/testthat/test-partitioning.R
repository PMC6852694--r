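test_that("particulate fraction matches hand arithmetic and limits", {
  # x/(1+x) with x = Kd*m, m converted mg/L -> kg/L (hand-checked)
  expect_equal(particulate_fraction(10^4.48, 15), 0.31176534,
               tolerance = 1e-7)
  expect_equal(particulate_fraction(10^4.85, 15), 0.51501479,
               tolerance = 1e-7)
  expect_equal(particulate_fraction(123456, 0), 0)
  expect_equal(particulate_fraction(0, 15), 0)
})

test_that("particulate fraction is monotone in both KD and solids", {
  kds <- 10^seq(2, 7, by = 0.5)
  ms <- c(0.5, 2, 5, 15, 60, 200)
  for (m in ms) {
    expect_true(all(diff(particulate_fraction(kds, m)) > 0))
  }
  for (kd in kds) {
    expect_true(all(diff(particulate_fraction(kd, ms)) > 0))
  }
})

test_that("isotherm KD anchors, varies monotonically and clamps", {
  pm <- partitioning_model(mode = "isotherm")
  expect_equal(isotherm_kd(pm$isotherm_ref_conc_ug_L, pm),
               10^pm$isotherm_ref_log_kd)
  cc <- c(0.05, 0.22, 1, 5, 17, 60)
  kd <- isotherm_kd(cc, pm)
  expect_true(all(diff(kd) <= 0))              # non-increasing in conc
  expect_true(all(log10(kd) >= pm$isotherm_log_kd_band[1] - 1e-12))
  expect_true(all(log10(kd) <= pm$isotherm_log_kd_band[2] + 1e-12))

  lin <- partitioning_model(mode = "isotherm", isotherm_exponent = 1,
                            isotherm_log_kd_band = NULL)
  expect_equal(isotherm_kd(c(0.1, 1, 100), lin),
               rep(10^lin$isotherm_ref_log_kd, 3))

  unclamped <- partitioning_model(mode = "isotherm",
                                  isotherm_log_kd_band = NULL)
  expect_equal(
    log10(isotherm_kd(1.7, unclamped)),
    unclamped$isotherm_ref_log_kd + (unclamped$isotherm_exponent - 1) *
      log10(0.1))

  expect_error(isotherm_kd(0, pm), "> 0")
  expect_error(isotherm_kd(17, partitioning_model()), "isotherm")
})

test_that("extra DOC lowers the operational isotherm KD", {
  pm <- partitioning_model(mode = "isotherm")
  kd2 <- isotherm_kd(17, pm, doc_mg_L = 2)
  kd15 <- isotherm_kd(17, pm, doc_mg_L = 15)
  expect_lt(kd15, kd2)
  # factor is (1 + K*2)/(1 + K*15)
  kdoc <- pm$k_doc_conditional_L_mg
  expect_equal(kd15 / kd2, (1 + 2 * kdoc) / (1 + 15 * kdoc))
})

test_that("DOC complexation is strong at ambient DOC and monotone", {
  expect_equal(doc_complexed_fraction(0), 0)
  expect_gt(doc_complexed_fraction(2), 0.98)
  expect_gt(doc_complexed_fraction(15), doc_complexed_fraction(2))
})

test_that("speciation fractions always sum to one for positive inventory", {
  pm <- partitioning_model()
  scenarios <- list(
    anoxic = lake_scenario(),
    oxic = lake_scenario(sediment_redox = "oxic"),
    low_avs = lake_scenario(avs_umol_g = 1)
  )
  for (sc in scenarios) {
    for (inv in c(1, 1e4, 1e6, 1e7, 5e9)) {   # spans sub- to over-capacity
      br <- sediment_equilibrium(inv, sc, pm)
      expect_equal(sum(unlist(br$fractions)), 1, tolerance = 1e-9)
    }
  }
  zero <- sediment_equilibrium(0, lake_scenario(), pm)
  expect_equal(sum(unlist(zero$fractions)), 0)
})

test_that("anoxic sediment is sulfide-dominated with trace free copper", {
  pm <- partitioning_model()
  sc <- lake_scenario()
  # base-case spike fully transferred: 35 ug/L * 3 m water = 105000 ug/m2,
  # far below the AVS capacity of the layer
  br <- sediment_equilibrium(105000, sc, pm)
  expect_gt(br$fractions$particulate_sulfide, 0.99)
  expect_lt(br$free_ion_of_dissolved, 0.001)   # < 0.1 % of dissolved
  expect_gt(br$effective_log_kd, 6)            # >> the sulfide-free 3.53
})

test_that("oxic particulate copper apportions to POC/HFO/HMO as calibrated", {
  pm <- partitioning_model()
  sc <- lake_scenario(sediment_redox = "oxic")
  br <- sediment_equilibrium(105000, sc, pm)
  part <- br$fractions$particulate_poc + br$fractions$particulate_hfo +
    br$fractions$particulate_hmo
  expect_equal(br$fractions$particulate_sulfide, 0)
  expect_equal(100 * br$fractions$particulate_poc / part, 95.34,
               tolerance = 0.01)
  expect_equal(100 * br$fractions$particulate_hfo / part, 4.30,
               tolerance = 0.01)
  expect_equal(100 * br$fractions$particulate_hmo / part, 0.36,
               tolerance = 0.01)
})

test_that("phase coefficients give the sulfide-free sorptive KD", {
  pm <- partitioning_model()
  kd <- cufate:::phase_kd_L_kg(lake_scenario(), pm)
  expect_equal(log10(kd), 3.53, tolerance = 0.002)
})

test_that("sulfide-bound copper never exceeds stoichiometric AVS capacity", {
  sc <- lake_scenario(avs_umol_g = 1)
  for (stoich in c("CuS", "Cu2S")) {
    pm <- partitioning_model(sulfide_stoichiometry = stoich)
    cap <- sc$avs_umol_g * 1e-6 * 1000 *
      sc$sediment_solids_g_Lbulk * sc$sediment_depth_m *
      ifelse(stoich == "Cu2S", 2, 1) * 63.546 * 1e6
    for (inv in c(0.5, 0.99, 1.01, 3, 50) * cap) {
      br <- sediment_equilibrium(inv, sc, pm)
      expect_lte(br$fractions$particulate_sulfide * inv, cap * (1 + 1e-12))
    }
    # saturates exactly at capacity once exceeded
    br <- sediment_equilibrium(10 * cap, sc, pm)
    expect_equal(br$fractions$particulate_sulfide * 10 * cap, cap)
  }
})

test_that("hydroxide saturation index behaves as a diagnostic should", {
  pm <- partitioning_model()
  expect_lt(hydroxide_saturation_index(7, 0.01, pm), 0)
  expect_gt(hydroxide_saturation_index(8.5, 250, pm), 0)
  si <- vapply(seq(5, 10, by = 0.5), hydroxide_saturation_index,
               numeric(1), dissolved_inorganic_cu_ug_L = 50, model = pm)
  expect_true(all(diff(si) > 0))               # monotone in pH
  expect_error(hydroxide_saturation_index(7, 0, pm), "> 0")
  expect_error(hydroxide_saturation_index(13, 10, pm), "\\[2, 12\\]")
})
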