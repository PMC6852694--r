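test_that("noiseless exponentials are recovered exactly", {
  ts <- time_series(0:10, 20 * exp(-0.1 * 0:10))
  fit <- fit_first_order(ts)
  expect_equal(fit$k_per_d, 0.1, tolerance = 1e-10)
  expect_equal(fit$c0_ug_L, 20, tolerance = 1e-8)
  expect_lt(diff(fit$k_ci95), 1e-8)
  expect_true(fit$supported)

  nl <- fit_first_order(ts, method = "nonlinear")
  expect_rel_equal(nl$k_per_d, fit$k_per_d, rel = 0.01)
})

test_that("log-linear and nonlinear fits agree closely on clean data", {
  for (k in c(0.05, 0.2, 0.7)) {
    ts <- time_series(c(0, 1, 2, 4, 8, 16, 22), 35 * exp(-k * c(0, 1, 2, 4, 8, 16, 22)))
    ll <- fit_first_order(ts, "loglinear")
    nl <- fit_first_order(ts, "nonlinear")
    expect_rel_equal(nl$k_per_d, ll$k_per_d, rel = 0.01)
  }
})

test_that("an increasing series is flagged unsupported", {
  ts <- time_series(0:6, c(5, 5.5, 6.2, 6.6, 7.4, 8.1, 9))
  fit <- fit_first_order(ts)
  expect_false(fit$supported)
  expect_lt(fit$k_per_d, 0)
})

test_that("below-detection and non-positive samples are excluded", {
  tt <- 0:6
  cc <- 20 * exp(-0.3 * tt)
  cc[5] <- 0
  expect_warning(fit <- fit_first_order(time_series(tt, cc)),
                 "excluded")
  expect_equal(fit$n_points, 6)
  expect_equal(fit$k_per_d, 0.3, tolerance = 1e-9)

  flagged <- time_series(tt, cc + 1, below_dl = c(rep(FALSE, 5), TRUE,
                                                  TRUE))
  fit2 <- fit_first_order(flagged)
  expect_equal(fit2$n_points, 5)

  suppressWarnings(
    expect_error(fit_first_order(time_series(0:2, c(1, 0, 0))),
                 "at least 3"))
})

test_that("confidence intervals achieve near-nominal coverage", {
  # lognormal multiplicative noise is exactly normal on the log scale, so
  # the slope t-interval should cover the true rate ~95% of the time
  set.seed(101)
  k_true <- 0.2
  tt <- c(0, 1, 2, 4, 8, 16, 22)
  sdlog <- sqrt(log(1 + 0.1^2))
  hits <- vapply(1:300, function(i) {
    cc <- 20 * exp(-k_true * tt) *
      stats::rlnorm(length(tt), -sdlog^2 / 2, sdlog)
    ci <- fit_first_order(time_series(tt, cc))$k_ci95
    ci[1] <= k_true && k_true <= ci[2]
  }, logical(1))
  expect_gt(mean(hits), 0.90)
  expect_lt(mean(hits), 0.99)
})

test_that("removal times propagate from the rate with antitone bounds", {
  rt <- removal_times_from_fit(0.0091)
  expect_equal(rt$t50_d, 76.170, tolerance = 1e-4)
  expect_equal(rt$t70_d, 132.30, tolerance = 1e-4)
  expect_equal(removal_times_from_fit(log(2))$t50_d, 1)

  fit <- structure(list(k_per_d = 0.1, k_ci95 = c(0.05, 0.2),
                        supported = TRUE), class = "first_order_fit")
  rt2 <- removal_times_from_fit(fit)
  expect_equal(rt2$t50_ci, log(2) / c(0.2, 0.05))   # upper k -> lower t
  expect_lt(rt2$t50_ci[1], rt2$t50_d)
  expect_gt(rt2$t50_ci[2], rt2$t50_d)
  expect_equal(rt2$t70_d / rt2$t50_d, log(100 / 30) / log(2))

  bad <- removal_times_from_fit(-0.05)
  expect_true(is.na(bad$t50_d))
  expect_match(bad$note, "non-positive")
})

test_that("interpolation reproduces the hand-worked crossings", {
  expect_equal(
    interpolate_removal_time(time_series(0:2, c(10, 5, 2.5)))$t50_d, 1)
  # between (2 d, 0.6) and (4 d, 0.4): 50% at 3 d exactly
  expect_equal(
    interpolate_removal_time(time_series(c(0, 2, 4), c(10, 6, 4)))$t50_d,
    3)
  flat <- interpolate_removal_time(time_series(0:3, c(10, 9, 8.5, 8)))
  expect_true(is.na(flat$t50_d))
  expect_match(flat$note, "50% removal not observed")

  expect_warning(
    interpolate_removal_time(
      time_series(0:4, c(10, 4, 6, 3, 2))), "multiple crossings")
})

test_that("the reference is the post-dose maximum, not the first sample", {
  # delayed-mixing peak at t = 1
  ts <- time_series(c(0, 1, 2, 3, 4), c(6, 12, 6, 3, 1.5))
  rt <- interpolate_removal_time(ts)
  expect_equal(rt$t50_d, 1)   # one day after the 12 ug/L peak
})

test_that("removal summary pools duplicates and picks methods", {
  tt <- c(0, 1, 2, 4, 8, 16, 22)
  clean <- function(k) time_series(tt, 30 * exp(-k * tt))
  single <- removal_summary(list(sys = clean(0.25)))
  dup <- removal_summary(list(sys = list(clean(0.25), clean(0.25))))
  expect_equal(dup$t50_d, single$t50_d)
  expect_identical(dup$method, "fit")

  rising <- time_series(0:5, c(4, 4.4, 4.8, 5.4, 6, 6.6))
  tab <- removal_summary(list(up = rising))
  expect_identical(tab$method, "interpolation")
  expect_match(tab$note, "not observed")

  # seeded synthetic systems: true t50 inside the reported interval
  set.seed(7)
  specs <- list(a = 0.1, b = 0.3, c = 0.6)
  coll <- lapply(specs, function(k) {
    generate_spike_series(synth_spec(k_per_d = k, c0_ug_L = 40,
                                     cv = 0.08, seed = sample.int(1e6, 1)))
  })
  tab2 <- removal_summary(coll)
  for (i in seq_along(specs)) {
    t50_true <- log(2) / specs[[i]]
    expect_gt(t50_true, tab2$t50_lo[i])
    expect_lt(t50_true, tab2$t50_hi[i])
  }
})
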