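test_that("nitrogen balance reproduces the hand-computed cases", {
  # equal-volume case: N2 fractions match so VE = VI and RER = 1
  a <- compute_gas_exchange(0.2065, 0.0034, 0.2095, 0.0004, 3000)
  expect_equal(a$ve_dry_ml_min, 3000)
  expect_equal(a$vo2_ml_h, 540)
  expect_equal(a$vco2_ml_h, 540)

  b <- compute_gas_exchange(0.2050, 0.0040, 0.2095, 0.0004, 3000)
  expect_equal(b$ve_dry_ml_min, 3000 * 0.7901 / 0.7910, tolerance = 1e-12)
  expect_equal(b$vo2_ml_h, 852.0, tolerance = 5e-5)
  expect_equal(b$vco2_ml_h, 647.2, tolerance = 5e-5)

  # no animal: excurrent equals incurrent
  z <- compute_gas_exchange(0.2095, 0.0004, 0.2095, 0.0004, 3000)
  expect_equal(z$vo2_ml_h, 0)
  expect_equal(z$vco2_ml_h, 0)
})

test_that("forward mixing then inversion recovers any truth to 1e-9 (gases)", {
  set.seed(101)
  n <- 2000
  vo2 <- runif(n, 50, 3000)
  vco2 <- vo2 * runif(n, 0.7, 1.0)
  ewl <- runif(n, 50, 3000)
  flow <- runif(n, 2500, 4600)
  mix <- forward_mix(vo2, vco2, ewl, flow)
  inv <- compute_gas_exchange(mix$fe_o2, mix$fe_co2,
                              flow_stpd_ml_min = flow)
  expect_lt(max(abs(inv$vo2_ml_h / vo2 - 1)), 1e-9)
  expect_lt(max(abs(inv$vco2_ml_h / vco2 - 1)), 1e-9)
  ewl_back <- compute_ewl(mix$rh_pct, 25, inv$ve_dry_ml_min)
  expect_lt(max(abs(ewl_back / ewl - 1)), 1e-6)
})

test_that("RER = 1 implies dry excurrent flow equals incurrent flow exactly", {
  set.seed(7)
  for (i in 1:20) {
    vo2 <- runif(1, 100, 2000)
    mix <- forward_mix(vo2, vo2, 500, 3000)
    inv <- compute_gas_exchange(mix$fe_o2, mix$fe_co2, flow_stpd_ml_min = 3000)
    expect_equal(inv$ve_dry_ml_min, 3000, tolerance = 1e-12)
  }
})

test_that("impossible fractions are rejected", {
  expect_error(compute_gas_exchange(0.7, 0.4, flow_stpd_ml_min = 1000), ">= 1")
  expect_error(compute_gas_exchange(0.2, -0.01, flow_stpd_ml_min = 1000), "fractions")
  expect_error(compute_gas_exchange(0.2, 0.003, flow_stpd_ml_min = 0), "flow")
})

test_that("psychrometric EWL matches the hand computation and scales in flow", {
  expect_equal(compute_ewl(0, 25, 3000), 0)
  expect_equal(saturation_vp(25), 3.1616, tolerance = 1e-4)
  e1 <- compute_ewl(25, 25, 2996.6)
  expect_equal(e1, 1136, tolerance = 5e-4)
  expect_equal(compute_ewl(25, 25, 2 * 2996.6), 2 * e1)
  expect_error(compute_ewl(100, 25, 1000, bp_kPa = 2), "pressure")
  expect_error(compute_ewl(120, 25, 1000), "rh")
})

test_that("EWL is monotone in RH and probe temperature", {
  rh <- seq(1, 99, 2)
  e_rh <- compute_ewl(rh, 25, 3000)
  expect_true(all(diff(e_rh) > 0))
  tt <- seq(5, 40, 0.5)
  e_t <- compute_ewl(30, tt, 3000)
  expect_true(all(diff(e_t) > 0))
})

test_that("baseline model anchors at the two window means", {
  tr <- local({
    n <- 81
    resp_trace(data.frame(
      time_s = 15 * seq_len(3 * n),
      o2_frac = c(rep(0.2090, n), rep(0.206, n), rep(0.2100, n)),
      co2_frac = 0.0004, rh_pct = 1, t_probe_C = 25, flow_stpd_ml_min = 3000,
      phase = rep(c("baseline_pre", "animal", "baseline_post"), each = n)),
      list(barometric_pressure_kPa = 101.325, sample_interval_s = 15))
  })
  bl <- fit_baseline(tr)
  ch <- bl$channels$o2_frac
  expect_equal(ch$pre_mean, 0.2090)
  expect_equal(ch$post_mean, 0.2100)
  # drift line passes through the two anchors
  expect_equal(predict_baseline(bl, "o2_frac", ch$t_pre), 0.2090)
  expect_equal(predict_baseline(bl, "o2_frac", ch$t_post), 0.2100)
  expect_equal(ch$slope, 0.0010 / (ch$t_post - ch$t_pre))

  # zero drift: constant reference everywhere
  tr0 <- tr
  tr0$data$o2_frac <- 0.2095
  bl0 <- fit_baseline(tr0)
  expect_equal(predict_baseline(bl0, "o2_frac", c(0, 1e4, 5e4)),
               rep(0.2095, 3))
})

test_that("short baselines are rejected by name", {
  s <- preset_scenarios()$arid
  set.seed(2)
  truth <- steady_physiology(s, draw_individuals(s)[1, ], 14)
  tr <- simulate_trace(truth, fast_chamber(baseline_s = 300), seed = 2)
  expect_error(fit_baseline(tr), "baseline_pre")
})

test_that("animal phase identical to baselines yields an all-zero series", {
  n <- 81
  tr <- resp_trace(data.frame(
    time_s = 15 * seq_len(3 * n),
    o2_frac = 0.2095, co2_frac = 0.0004, rh_pct = 1, t_probe_C = 25,
    flow_stpd_ml_min = 3000,
    phase = rep(c("baseline_pre", "animal", "baseline_post"), each = n)),
    list(barometric_pressure_kPa = 101.325, sample_interval_s = 15))
  ser <- correct_series(tr, fit_baseline(tr))
  expect_equal(ser$vo2_ml_h, rep(0, n))
  expect_equal(ser$vco2_ml_h, rep(0, n))
  expect_equal(ser$ewl_mg_h, rep(0, n))
})

test_that("linear analyzer drift is removed without bias", {
  s <- preset_scenarios()$arid
  cfg <- pipeline_config()
  set.seed(33)
  ind <- draw_individuals(s)[1, ]
  truth <- steady_physiology(s, ind, 18)
  # drift 10x the default, no noise: recovery should still be essentially exact
  ch <- fast_chamber(noise_sd = c(o2 = 0, co2 = 0, rh = 0),
                     drift_per_h = c(o2 = -2e-3, co2 = 5e-4, rh = 2))
  tr <- simulate_trace(truth, ch, seed = 4)
  ser <- correct_series(tr, fit_baseline(tr))
  w <- find_steady_window(ser, min_start_s = 8 * 60 * 8000 / 3000)
  expect_lt(abs(w$means[["vo2_ml_h"]] / truth$vo2_ml_h - 1), 2e-3)
  expect_lt(abs(w$means[["ewl_mg_h"]] / truth$ewl_mg_h - 1), 2e-3)
})
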