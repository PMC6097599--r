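test_that("Scholander closure: VO2 at the TNZ lower bound equals BMR", {
  s <- preset_scenarios()$arid
  mean_ind <- data.frame(animal_id = "m", mass_g = s$mass_mean_g,
                         bmr_mult = 1, ewl_mult = 1, tb_offset_C = 0)
  at_lcT <- steady_physiology(s, mean_ind, s$tnz_C[1])
  bmr_whole <- s$bmr_mi * s$mass_mean_g^s$mr_exponent
  expect_equal(at_lcT$vo2_ml_h, bmr_whole, tolerance = 1e-12)
  # approached from below as well (continuity of the conductance line)
  eps <- steady_physiology(s, mean_ind, s$tnz_C[1] - 1e-9)
  expect_equal(eps$vo2_ml_h, bmr_whole, tolerance = 1e-6)
})

test_that("below the TNZ, 1 degC colder raises mass-specific MHP by cwet", {
  s <- preset_scenarios()$montane
  mean_ind <- data.frame(animal_id = "m", mass_g = s$mass_mean_g,
                         bmr_mult = 1, ewl_mult = 1, tb_offset_C = 0)
  ta <- c(20, 19, 12, 11)
  ph <- steady_physiology(s, mean_ind, ta)
  mhp_ms <- metabolic_heat(ph$vo2_ml_h, ph$rer) / s$mass_mean_g
  expect_equal(mhp_ms[2] - mhp_ms[1], ph$cwet_true[1], tolerance = 1e-9)
  expect_equal(mhp_ms[4] - mhp_ms[3], ph$cwet_true[1], tolerance = 1e-9)
  # within the TNZ VO2 is flat at BMR; above it Tb and EWL rise
  inzone <- steady_physiology(s, mean_ind, c(s$tnz_C[1], mean(s$tnz_C), s$tnz_C[2]))
  expect_equal(diff(inzone$vo2_ml_h), c(0, 0))
  hot <- steady_physiology(s, mean_ind, c(s$tnz_C[2], s$tnz_C[2] + 3))
  expect_gt(hot$vo2_ml_h[2], hot$vo2_ml_h[1])
  expect_gt(hot$tb_C[2], hot$tb_C[1])
  expect_gt(hot$ewl_mg_h[2] / hot$ewl_mg_h[1], exp(0.14 * 3))
})

test_that("supplying cwet derives the TNZ lower bound through the closure", {
  s <- endotherm_scenario("x", cwet_J_g_h_C = 0.7, tb_C = 35, bmr_mi = 2.0,
                          mass_mean_g = 1800, tnz_C = c(20, 31))
  mhp_ms <- 2.0 * 1800^(0.74 - 1) * oxycal_coef(0.85)
  expect_equal(s$tnz_C[1], 35 - mhp_ms / 0.7)
  mean_ind <- data.frame(animal_id = "m", mass_g = 1800, bmr_mult = 1,
                         ewl_mult = 1, tb_offset_C = 0)
  expect_equal(steady_physiology(s, mean_ind, 20)$cwet_true[1], 0.7,
               tolerance = 1e-12)
})

test_that("washout follows the first-order law exactly", {
  ch <- chamber_config(volume_ml = 8000, flow_ml_min = 3000,
                       sample_interval_s = 15,
                       noise_sd = c(o2 = 0, co2 = 0, rh = 0),
                       drift_per_h = c(o2 = 0, co2 = 0, rh = 0))
  tau_s <- 60 * 8000 / 3000  # 2.667 min
  s <- preset_scenarios()$arid
  mean_ind <- data.frame(animal_id = "m", mass_g = 1800, bmr_mult = 1,
                         ewl_mult = 1, tb_offset_C = 0)
  truth <- steady_physiology(s, mean_ind, 22)
  tr <- simulate_trace(truth, ch, seed = 1)
  d <- tr$data[tr$data$phase == "animal", ]
  t_entry <- max(tr$data$time_s[tr$data$phase == "baseline_pre"])
  fi <- 0.2095
  # steady-state target from the final sample (>= 8 tau: residual < 4e-4)
  f_ss <- d$o2_frac[nrow(d)]
  pred <- f_ss + (fi - f_ss) * exp(-(d$time_s - t_entry) / tau_s)
  expect_equal(d$o2_frac, pred, tolerance = 1e-9)
  # discrete update equals the closed form: F(t+dt) relates to F(t) by e^(-dt/tau)
  resid <- d$o2_frac - f_ss
  expect_equal(resid[-1], resid[-length(resid)] * exp(-15 / tau_s),
               tolerance = 1e-9)
  # 95.0% of the step is covered at 3 tau
  at3 <- which.min(abs((d$time_s - t_entry) - 3 * tau_s))
  frac <- (d$o2_frac[at3] - fi) / (f_ss - fi)
  expect_equal(frac, 1 - exp(-(d$time_s[at3] - t_entry) / tau_s),
               tolerance = 1e-9)
  expect_equal(1 - exp(-3), 0.950, tolerance = 3e-4)
})

test_that("traces are byte-identical under equal seeds", {
  s <- preset_scenarios()$tropical
  set.seed(6)
  ind <- draw_individuals(s)[1, ]
  truth <- steady_physiology(s, ind, 30)
  t1 <- simulate_trace(truth, fast_chamber(), seed = 99)
  t2 <- simulate_trace(truth, fast_chamber(), seed = 99)
  expect_identical(t1$data, t2$data)
  expect_identical(t1$meta, t2$meta)
  t3 <- simulate_trace(truth, fast_chamber(), seed = 100)
  expect_false(identical(t1$data, t3$data))
})

test_that("zero-noise round trip recovers truth to 0.1%", {
  ch <- chamber_config(animal_s = 7200,
                       noise_sd = c(o2 = 0, co2 = 0, rh = 0),
                       drift_per_h = c(o2 = 0, co2 = 0, rh = 0),
                       tb_meas_sd_C = 0)
  cfg <- pipeline_config()
  s <- preset_scenarios()$arid
  set.seed(13)
  ind <- draw_individuals(s)[2, ]
  for (ta in c(10, 26, 34)) {
    truth <- steady_physiology(s, ind, ta)
    tr <- simulate_trace(truth, ch)
    ser <- correct_series(tr, fit_baseline(tr))
    w <- find_steady_window(ser, min_start_s = 8 * 60 * 8000 / 3000)
    expect_lt(abs(w$means[["vo2_ml_h"]] / truth$vo2_ml_h - 1), 1e-3)
    expect_lt(abs(w$means[["vco2_ml_h"]] / truth$vco2_ml_h - 1), 1e-3)
    expect_lt(abs(w$means[["ewl_mg_h"]] / truth$ewl_mg_h - 1), 1e-3)
  }
})

test_that("default cohort has one trace per population x individual x Ta", {
  ch <- fast_chamber()
  cohort <- generate_cohort(chamber = ch, seed = 1)
  expect_identical(length(cohort$traces), 4L * 6L * 8L)
  expect_identical(nrow(cohort$truth), 192L)
  expect_identical(sort(unique(cohort$truth$population_id)),
                   c("arid", "mesic_cool", "montane", "tropical"))
  # regenerating with the same seed is identical
  cohort2 <- generate_cohort(chamber = ch, seed = 1)
  expect_identical(cohort$truth, cohort2$truth)
  expect_identical(cohort$traces[[7]]$data, cohort2$traces[[7]]$data)
})

test_that("truth table satisfies the record identities", {
  cohort <- generate_cohort(chamber = fast_chamber(), seed = 2)
  tt <- cohort$truth
  expect_equal(tt$rer, tt$vco2_ml_h / tt$vo2_ml_h, tolerance = 1e-12)
  expect_equal(tt$rwe, tt$mwp_mg_h / tt$ewl_mg_h, tolerance = 1e-12)
  expect_equal(tt$mhp_J_h, tt$vo2_ml_h * oxycal_coef(tt$rer), tolerance = 1e-12)
  expect_equal(tt$ehl_J_h, 2.4 * tt$ewl_mg_h, tolerance = 1e-12)
  ok <- tt$conductance_defined
  expect_true(all(tt$cdry_J_g_h_C[ok] <= tt$cwet_J_g_h_C[ok]))
  expect_lt(max(abs(tt$vo2_mi * tt$mass_g^0.74 / tt$vo2_ml_h - 1)), 1e-12)
  expect_true(all(tt$vo2_ml_h > 0 & tt$ewl_mg_h > 0 & tt$tb_C > tt$ta_C - 40))
})
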