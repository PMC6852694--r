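# shared fixtures, built in code

base_setup <- function() builtin_scenarios()$euses_base

# scenario with all sediment feedback and washout off: the simulator must
# then collapse to the closed-form single-exponential settling solution
feedback_free_scenario <- function(...) {
  sc <- lake_scenario(resuspension_velocity_cm_yr = 0,
                      diffusion_mtc_m_d = 0, ...)
  sc
}

expect_rel_equal <- function(actual, expected, rel) {
  expect_lt(abs(actual / expected - 1), rel)
}
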