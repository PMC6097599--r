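#' Scholander-Irving endotherm scenario (generative truth)
#'
#' Describes one population's resting physiology across ambient temperature:
#' below the thermoneutral zone (TNZ) metabolic heat production follows the
#' conductance line MHP = C_wet (Tb - Ta) extrapolating to zero at Tb; within
#' the TNZ oxygen consumption sits at BMR; above the TNZ it rises linearly
#' and body temperature drifts upward. Evaporative water loss is flat up to
#' the TNZ upper bound and rises exponentially above it.
#'
#' Closure: wet conductance below the TNZ is derived per individual from the
#' Scholander identity (MHP on the conductance line at `tnz_C[1]` equals the
#' BMR-derived MHP), so BMR, Tb and the TNZ lower bound fully determine it.
#' If `cwet_J_g_h_C` is supplied instead, the TNZ lower bound is derived from
#' the same identity at the population means.
#'
#' @param population_id label, e.g. `"arid"`.
#' @param mass_mean_g,mass_sd_g body-mass distribution (g).
#' @param tb_C body-temperature set point (degC).
#' @param tb_slope_above Tb increase per degC of Ta above the TNZ upper bound.
#' @param bmr_mi mass-independent BMR (ml O2 g^-b h^-1 on `mr_exponent`).
#' @param mr_exponent,ewl_exponent allometric exponents (defaults 0.74, 0.68).
#' @param tnz_C thermoneutral zone `c(lower, upper)` (degC).
#' @param cwet_J_g_h_C optional wet conductance below TNZ; overrides
#'   `tnz_C[1]` via the closure identity.
#' @param ewl_basal_mi mass-independent basal EWL (mg H2O g^-b h^-1).
#' @param ewl_rise_rate exponential EWL rise per degC above the TNZ upper
#'   bound.
#' @param mr_rise_frac linear VO2 rise above the TNZ upper bound, as a
#'   fraction of BMR per degC.
#' @param rer respiratory exchange ratio, either one value or
#'   `c(below, tnz, above)` by Ta segment.
#' @param sd_log_bmr,sd_log_ewl,sd_tb between-individual SDs (log scale for
#'   rates, degC for Tb).
#' @param ta_grid_C ambient temperatures at which individuals are measured.
#' @param n_individuals individuals per population.
#' @return object of class `endotherm_scenario`.
#' @export
endotherm_scenario <- function(population_id,
                               mass_mean_g = 1800, mass_sd_g = 150,
                               tb_C = 35.0, tb_slope_above = 0.15,
                               bmr_mi = 2.0, mr_exponent = 0.74,
                               tnz_C = c(26, 31),
                               cwet_J_g_h_C = NULL,
                               ewl_basal_mi = 4.0, ewl_exponent = 0.68,
                               ewl_rise_rate = 0.20,
                               mr_rise_frac = 0.04,
                               rer = 0.85,
                               sd_log_bmr = 0.06, sd_log_ewl = 0.08,
                               sd_tb = 0.3,
                               ta_grid_C = c(6, 10, 14, 18, 22, 26, 30, 34),
                               n_individuals = 6,
                               table = conversion_table()) {
  if (length(rer) == 1) rer <- rep(rer, 3)
  names(rer) <- c("below", "tnz", "above")
  if (!is.null(cwet_J_g_h_C)) {
    # derive tnz lower bound from the closure identity at population means
    mhp_ms <- bmr_mi * mass_mean_g^(mr_exponent - 1) * oxycal_coef(rer[["tnz"]], table)
    tnz_C[1] <- tb_C - mhp_ms / cwet_J_g_h_C
  }
  if (tnz_C[1] >= tnz_C[2]) stop("tnz lower bound must be below upper bound")
  if (tnz_C[1] >= tb_C) stop("tnz lower bound must be below Tb")
  stopifnot(mass_mean_g > 0, bmr_mi > 0, ewl_basal_mi > 0)
  structure(list(population_id = population_id,
                 mass_mean_g = mass_mean_g, mass_sd_g = mass_sd_g,
                 tb_C = tb_C, tb_slope_above = tb_slope_above,
                 bmr_mi = bmr_mi, mr_exponent = mr_exponent,
                 tnz_C = tnz_C,
                 ewl_basal_mi = ewl_basal_mi, ewl_exponent = ewl_exponent,
                 ewl_rise_rate = ewl_rise_rate, mr_rise_frac = mr_rise_frac,
                 rer = rer,
                 sd_log_bmr = sd_log_bmr, sd_log_ewl = sd_log_ewl,
                 sd_tb = sd_tb,
                 ta_grid_C = ta_grid_C, n_individuals = n_individuals,
                 table = table),
            class = "endotherm_scenario")
}

#' Chamber and measurement-system configuration for the forward model
#'
#' @param volume_ml chamber volume (default 8000 cm^3).
#' @param flow_ml_min dry incurrent STPD flow (default 3000, within the
#'   2500-4600 ml min^-1 working range).
#' @param fi_o2,fi_co2 incurrent dry fractions.
#' @param bp_kPa barometric pressure.
#' @param sample_interval_s sampling interval (default 15 s; instruments log
#'   every 10-30 s).
#' @param baseline_s pre/post baseline duration (default 1200 s = 20 min).
#' @param animal_s animal-phase duration (default 10800 s = 3 h).
#' @param noise_sd per-channel Gaussian analyzer noise SD
#'   (`o2`, `co2` as fractions; `rh` in %RH).
#' @param drift_per_h per-channel linear drift per hour (same units).
#' @param rh_background_pct residual humidity of the dried incurrent air
#'   (%RH, default 1; desiccants do not reach exactly 0).
#' @param tb_meas_sd_C SD of the post-trial cloacal Tb measurement (degC).
#' @return object of class `chamber_config`.
#' @export
chamber_config <- function(volume_ml = 8000, flow_ml_min = 3000,
                           fi_o2 = 0.2095, fi_co2 = 0.0004,
                           bp_kPa = 101.325, sample_interval_s = 15,
                           baseline_s = 1200, animal_s = 10800,
                           noise_sd = c(o2 = 1.5e-4, co2 = 1.0e-4, rh = 0.5),
                           drift_per_h = c(o2 = -2e-4, co2 = 5e-5, rh = 0.2),
                           rh_background_pct = 1,
                           tb_meas_sd_C = 0.1) {
  stopifnot(volume_ml > 0, flow_ml_min > 0, sample_interval_s > 0,
            all(noise_sd >= 0))
  structure(list(volume_ml = volume_ml, flow_ml_min = flow_ml_min,
                 fi_o2 = fi_o2, fi_co2 = fi_co2, bp_kPa = bp_kPa,
                 sample_interval_s = sample_interval_s,
                 baseline_s = baseline_s, animal_s = animal_s,
                 noise_sd = noise_sd, drift_per_h = drift_per_h,
                 rh_background_pct = rh_background_pct,
                 tb_meas_sd_C = tb_meas_sd_C),
            class = "chamber_config")
}

#' Draw per-individual random effects for a scenario
#'
#' Uses the current RNG stream (set a seed upstream for reproducibility).
#' Rates get lognormal multipliers, Tb a Gaussian offset, mass a truncated
#' Gaussian.
#'
#' @param scenario an [endotherm_scenario()].
#' @param n number of individuals (default: the scenario's).
#' @return data.frame with `animal_id`, `mass_g`, `bmr_mult`, `ewl_mult`,
#'   `tb_offset_C`.
#' @export
draw_individuals <- function(scenario, n = scenario$n_individuals) {
  mass <- stats::rnorm(n, scenario$mass_mean_g, scenario$mass_sd_g)
  mass <- pmax(mass, 0.5 * scenario$mass_mean_g)
  data.frame(
    animal_id = sprintf("%s_%02d", scenario$population_id, seq_len(n)),
    mass_g = mass,
    bmr_mult = exp(stats::rnorm(n, 0, scenario$sd_log_bmr)),
    ewl_mult = exp(stats::rnorm(n, 0, scenario$sd_log_ewl)),
    tb_offset_C = stats::rnorm(n, 0, scenario$sd_tb),
    stringsAsFactors = FALSE)
}

scenario_rer <- function(scenario, ta) {
  ifelse(ta < scenario$tnz_C[1], scenario$rer[["below"]],
         ifelse(ta <= scenario$tnz_C[2], scenario$rer[["tnz"]],
                scenario$rer[["above"]]))
}

#' Resting steady-state physiology of one individual at one Ta
#'
#' Evaluates the scenario's Scholander-Irving structure: below the TNZ the
#' conductance line (closure-derived, see [endotherm_scenario()]); within it
#' BMR; above it a linear VO2 rise with a Tb drift and exponential EWL rise.
#' VCO2 = RER x VO2 throughout.
#'
#' @param scenario an [endotherm_scenario()].
#' @param individual one row of [draw_individuals()] (defaults to the
#'   population-mean individual).
#' @param ta_C ambient temperature(s), degC.
#' @return data.frame with whole-animal `vo2_ml_h`, `vco2_ml_h`, `ewl_mg_h`,
#'   `tb_C`, plus `cwet_true` (mass-specific, below-TNZ) and `prwe_true_C`.
#' @export
steady_physiology <- function(scenario, individual = NULL, ta_C) {
  s <- scenario
  if (is.null(individual)) {
    individual <- data.frame(animal_id = paste0(s$population_id, "_mean"),
                             mass_g = s$mass_mean_g, bmr_mult = 1,
                             ewl_mult = 1, tb_offset_C = 0)
  }
  mass <- individual$mass_g
  tb_set <- s$tb_C + individual$tb_offset_C
  lower <- s$tnz_C[1]
  upper <- s$tnz_C[2]
  if (tb_set <= lower) stop("individual Tb fell below the TNZ lower bound")
  rer <- scenario_rer(s, ta_C)
  bmr_whole <- s$bmr_mi * individual$bmr_mult * mass^s$mr_exponent
  mhp_bmr <- bmr_whole * oxycal_coef(s$rer[["tnz"]], s$table)

  tb <- tb_set + pmax(0, ta_C - upper) * s$tb_slope_above
  vo2 <- ifelse(ta_C < lower,
                mhp_bmr * (tb_set - ta_C) / (tb_set - lower) /
                  oxycal_coef(s$rer[["below"]], s$table),
                ifelse(ta_C <= upper,
                       bmr_whole,
                       bmr_whole * (1 + s$mr_rise_frac * (ta_C - upper))))
  ewl_base <- s$ewl_basal_mi * individual$ewl_mult * mass^s$ewl_exponent
  ewl <- ewl_base * exp(s$ewl_rise_rate * pmax(0, ta_C - upper))
  cwet_true <- mhp_bmr / (mass * (tb_set - lower))
  # analytic PRWE from the below-TNZ linear branch of RWE(Ta)
  hyg <- hygric_coef(s$rer[["below"]], s$table)
  oxy <- oxycal_coef(s$rer[["below"]], s$table)
  prwe <- tb_set - (tb_set - lower) * ewl_base * oxy / (mhp_bmr * hyg)
  data.frame(animal_id = individual$animal_id, ta_C = ta_C, tb_C = tb,
             vo2_ml_h = vo2, vco2_ml_h = rer * vo2, ewl_mg_h = ewl,
             rer = rer, mass_g = mass, cwet_true = cwet_true,
             prwe_true_C = prwe, stringsAsFactors = FALSE)
}

# steady-state excurrent state implied by a physiological truth
excurrent_steady_state <- function(truth, chamber) {
  vi <- chamber$flow_ml_min
  vo2 <- truth$vo2_ml_h / 60
  vco2 <- truth$vco2_ml_h / 60
  ve <- vi - vo2 + vco2
  vw <- truth$ewl_mg_h / 60 / WATER_MG_PER_MMOL * GAS_ML_PER_MMOL
  list(fe_o2 = (vi * chamber$fi_o2 - vo2) / ve,
       fe_co2 = (vi * chamber$fi_co2 + vco2) / ve,
       pw_kPa = chamber$bp_kPa * vw / (ve + vw),
       ve_dry = ve)
}

#' Simulate one chamber trace from a physiological truth
#'
#' Forward model of the measurement system: steady-state excurrent fractions
#' from the dry-nitrogen mass balance and the psychrometric vapor model, a
#' first-order chamber washout \eqn{F(t+\Delta) = F_{ss} + (F(t) -
#' F_{ss})e^{-\Delta\,flow/volume}} from incurrent composition at animal
#' entry, instantaneous (bypass-style) pre/post baselines at incurrent
#' composition, then per-channel linear drift and Gaussian analyzer noise.
#' Fully reproducible given `seed`.
#'
#' @param truth one row from [steady_physiology()].
#' @param chamber a [chamber_config()].
#' @param meta extra trace metadata (population_id, ta_target_C, ...).
#' @param seed optional integer seed; when NULL the current RNG stream is
#'   used (so cohort generation is reproducible from a single seed).
#' @return a [resp_trace()].
#' @export
simulate_trace <- function(truth, chamber, meta = list(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dt <- chamber$sample_interval_s
  n_pre <- max(2L, round(chamber$baseline_s / dt))
  n_animal <- max(2L, round(chamber$animal_s / dt))
  n_post <- n_pre
  n <- n_pre + n_animal + n_post
  time_s <- dt * seq_len(n)
  phase <- rep(c("baseline_pre", "animal", "baseline_post"),
               c(n_pre, n_animal, n_post))
  ss <- excurrent_steady_state(truth, chamber)
  ta <- truth$ta_C

  k_per_s <- chamber$flow_ml_min / chamber$volume_ml / 60
  t_entry <- time_s[n_pre + 1] - dt  # washout starts when the animal goes in
  wash <- function(start, target) {
    x <- rep(start, n)
    ia <- (n_pre + 1):(n_pre + n_animal)
    x[ia] <- target + (start - target) * exp(-k_per_s * (time_s[ia] - t_entry))
    x  # baselines read incurrent air directly (bypass), no washout there
  }
  o2 <- wash(chamber$fi_o2, ss$fe_o2)
  co2 <- wash(chamber$fi_co2, ss$fe_co2)
  # background vapor of the dried incurrent air rides on top of the
  # animal-added vapor and is removed downstream by baseline correction
  pw_bg <- chamber$rh_background_pct %||% 0
  pw <- wash(0, ss$pw_kPa)
  rh <- pw_bg + 100 * pw / saturation_vp(ta)

  hrs <- time_s / 3600
  o2 <- o2 + chamber$drift_per_h[["o2"]] * hrs + stats::rnorm(n, 0, chamber$noise_sd[["o2"]])
  co2 <- co2 + chamber$drift_per_h[["co2"]] * hrs + stats::rnorm(n, 0, chamber$noise_sd[["co2"]])
  rh <- rh + chamber$drift_per_h[["rh"]] * hrs + stats::rnorm(n, 0, chamber$noise_sd[["rh"]])

  d <- data.frame(time_s = time_s,
                  o2_frac = pmax(o2, 0),
                  co2_frac = pmax(co2, 0),
                  rh_pct = pmin(pmax(rh, 0), 100),
                  t_probe_C = ta,
                  flow_stpd_ml_min = chamber$flow_ml_min,
                  phase = phase,
                  stringsAsFactors = FALSE)
  mass <- truth$mass_g
  tb_meas <- truth$tb_C + stats::rnorm(1, 0, chamber$tb_meas_sd_C)
  base_meta <- list(animal_id = truth$animal_id,
                    mass_before_g = round(mass * 1.005),
                    mass_after_g = round(mass * 0.995),
                    tb_final_C = round(tb_meas, 1),
                    ta_target_C = ta,
                    chamber_volume_ml = chamber$volume_ml,
                    barometric_pressure_kPa = chamber$bp_kPa,
                    sample_interval_s = dt,
                    calibrated = "yes")
  for (key in names(meta)) base_meta[[key]] <- meta[[key]]
  resp_trace(d, base_meta)
}

#' Generate a multi-population cohort of traces with generative truth
#'
#' One trace per population x individual x ambient temperature, plus a truth
#' table carrying every standard physiological variable computed from the
#' generative truth (so end-to-end recovery can be scored). With the four
#' default presets, 6 individuals and 8 Ta levels this yields 192 traces.
#'
#' @param scenarios list of [endotherm_scenario()]s (default
#'   [preset_scenarios()]).
#' @param chamber a [chamber_config()].
#' @param seed integer seed governing every random draw.
#' @param dropout fraction of individual x Ta combinations dropped at random
#'   (irregular measurement grids); default 0.
#' @param out_dir optional directory; when given, traces are written as
#'   canonical CSVs and the truth table as `truth.csv`.
#' @return list with `traces` (named list of [resp_trace()]) and `truth`
#'   (data.frame, one row per trace).
#' @export
generate_cohort <- function(scenarios = preset_scenarios(),
                            chamber = chamber_config(), seed = 1,
                            dropout = 0, out_dir = NULL) {
  set.seed(seed)
  traces <- list()
  truth_rows <- list()
  for (s in scenarios) {
    indiv <- draw_individuals(s)
    for (i in seq_len(nrow(indiv))) {
      for (ta in s$ta_grid_C) {
        if (dropout > 0 && stats::runif(1) < dropout) next
        tr_truth <- steady_physiology(s, indiv[i, ], ta)
        trace <- simulate_trace(tr_truth, chamber,
                                meta = list(population_id = s$population_id))
        nm <- sprintf("%s_ta%02d", tr_truth$animal_id, round(ta))
        traces[[nm]] <- trace
        truth_rows[[nm]] <- truth_record(tr_truth, s)
      }
    }
  }
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(traces)) {
      write_trace(traces[[nm]], file.path(out_dir, paste0(nm, ".csv")))
    }
    utils::write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
  }
  list(traces = traces, truth = truth)
}

# expand a generative truth row into the standard physiological record
truth_record <- function(tr, scenario) {
  tab <- scenario$table
  exps <- scaling_exponents(mr = scenario$mr_exponent,
                            ewl = scenario$ewl_exponent)
  rer <- tr$rer
  mhp <- metabolic_heat(tr$vo2_ml_h, rer, tab)
  mwp <- metabolic_water(tr$vo2_ml_h, rer, tab)
  ehl <- evaporative_heat(tr$ewl_mg_h, tab)
  cond <- thermal_conductance(mhp, ehl, tr$tb_C, tr$ta_C, tr$mass_g)
  data.frame(
    animal_id = tr$animal_id, population_id = scenario$population_id,
    ta_C = tr$ta_C, tb_C = tr$tb_C,
    mass_g = tr$mass_g,
    vo2_ml_h = tr$vo2_ml_h, vco2_ml_h = tr$vco2_ml_h, ewl_mg_h = tr$ewl_mg_h,
    rer = rer, mhp_J_h = mhp, mwp_mg_h = mwp, ehl_J_h = ehl,
    cwet_J_g_h_C = cond$cwet, cdry_J_g_h_C = cond$cdry,
    rwe = mwp / tr$ewl_mg_h,
    vo2_mi = mass_independent(tr$vo2_ml_h, tr$mass_g, exps[["mr"]]),
    ewl_mi = mass_independent(tr$ewl_mg_h, tr$mass_g, exps[["ewl"]]),
    cwet_mi = if (cond$defined)
      mass_independent(cond$cwet * tr$mass_g, tr$mass_g, exps[["cwet"]])
      else NA_real_,
    prwe_true_C = tr$prwe_true_C,
    conductance_defined = cond$defined,
    stringsAsFactors = FALSE)
}

#' Four illustrative population presets
#'
#' Qualitative climate archetypes for a medium-sized marsupial: `arid` (low
#' BMR and EWL, favourable water economy), `mesic_cool`, `montane` (high Tb
#' and BMR), `tropical` (high EWL, steep heat response). Parameter values are
#' round numbers chosen to span realistic contrasts; they are not estimates
#' for any particular population.
#'
#' @return named list of four [endotherm_scenario()]s.
#' @export
preset_scenarios <- function() {
  list(
    arid = endotherm_scenario("arid", mass_mean_g = 1800, mass_sd_g = 150,
                              tb_C = 34.8, bmr_mi = 2.0, ewl_basal_mi = 3.1,
                              tnz_C = c(26, 31), ewl_rise_rate = 0.26,
                              mr_rise_frac = 0.03),
    mesic_cool = endotherm_scenario("mesic_cool", mass_mean_g = 2700,
                                    mass_sd_g = 220, tb_C = 35.0,
                                    bmr_mi = 1.8, ewl_basal_mi = 4.1,
                                    tnz_C = c(25, 30), ewl_rise_rate = 0.16,
                                    mr_rise_frac = 0.04),
    montane = endotherm_scenario("montane", mass_mean_g = 2900,
                                 mass_sd_g = 240, tb_C = 36.2,
                                 bmr_mi = 2.8, ewl_basal_mi = 6.5,
                                 tnz_C = c(24, 30), ewl_rise_rate = 0.15,
                                 mr_rise_frac = 0.04),
    tropical = endotherm_scenario("tropical", mass_mean_g = 1600,
                                  mass_sd_g = 140, tb_C = 36.0,
                                  tb_slope_above = 0.25, bmr_mi = 2.5,
                                  ewl_basal_mi = 5.4, tnz_C = c(26, 31),
                                  ewl_rise_rate = 0.22, mr_rise_frac = 0.06)
  )
}
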