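#' Oxy-calorific, hygric and latent-heat conversion table
#'
#' Converts oxygen consumption to metabolic heat and water production at the
#' measured respiratory exchange ratio, and evaporative water loss to
#' evaporative heat loss. Coefficients are linear interpolations between two
#' RER knots (pure lipid 0.71, pure carbohydrate 1.00); values follow the
#' conventional respirometry tables and are configuration, not constants of
#' nature. Lookups clamp RER to the knot domain.
#'
#' @param oxycal J per ml O2 at the two RER knots, `c(rer_lo, j_lo, rer_hi, j_hi)`.
#' @param hygric mg H2O per ml O2 at the two RER knots.
#' @param latent_heat_J_mg latent heat of evaporation (J per mg H2O),
#'   default 2.4.
#' @return object of class `conversion_table`.
#' @export
conversion_table <- function(oxycal = c(0.71, 19.6, 1.00, 21.1),
                             hygric = c(0.71, 0.53, 1.00, 0.67),
                             latent_heat_J_mg = 2.4) {
  for (tb in list(oxycal, hygric)) {
    if (tb[3] <= tb[1] || tb[4] < tb[2]) {
      stop("conversion knots must be increasing in RER and non-decreasing in value")
    }
  }
  if (latent_heat_J_mg <= 0) stop("latent heat must be positive")
  structure(list(oxycal = oxycal, hygric = hygric,
                 latent_heat_J_mg = latent_heat_J_mg),
            class = "conversion_table")
}

interp_knots <- function(rer, knots) {
  r <- pmin(pmax(rer, knots[1]), knots[3])
  knots[2] + (r - knots[1]) * (knots[4] - knots[2]) / (knots[3] - knots[1])
}

#' Oxy-calorific coefficient (J per ml O2) at a given RER
#' @param rer respiratory exchange ratio (clamped to the table domain).
#' @param table a [conversion_table()].
#' @export
oxycal_coef <- function(rer, table = conversion_table()) {
  interp_knots(rer, table$oxycal)
}

#' Hygric coefficient (mg metabolic H2O per ml O2) at a given RER
#' @inheritParams oxycal_coef
#' @export
hygric_coef <- function(rer, table = conversion_table()) {
  interp_knots(rer, table$hygric)
}

#' Respiratory exchange ratio
#'
#' VCO2/VO2. Values outside the physiological range [0.7, 1.0] are returned
#' unchanged with a warning (conversion lookups clamp separately).
#'
#' @param vo2_ml_h oxygen consumption (must be > 0).
#' @param vco2_ml_h carbon dioxide production.
#' @export
compute_rer <- function(vo2_ml_h, vco2_ml_h) {
  if (any(vo2_ml_h <= 0)) stop("vo2 must be positive to form RER")
  rer <- vco2_ml_h / vo2_ml_h
  out <- rer < 0.7 | rer > 1.0
  if (any(out)) {
    warning(sum(out), " RER value(s) outside [0.7, 1.0]; returned as-is")
  }
  rer
}

#' Metabolic heat production
#'
#' MHP = VO2 x oxy-calorific coefficient at the measured RER (J h^-1).
#'
#' @param vo2_ml_h oxygen consumption (ml STPD h^-1, >= 0).
#' @param rer respiratory exchange ratio.
#' @param table a [conversion_table()].
#' @export
metabolic_heat <- function(vo2_ml_h, rer, table = conversion_table()) {
  if (any(vo2_ml_h < 0)) stop("vo2 must be non-negative")
  vo2_ml_h * oxycal_coef(rer, table)
}

#' Metabolic water production
#'
#' MWP = VO2 x hygric coefficient at the measured RER (mg H2O h^-1).
#'
#' @inheritParams metabolic_heat
#' @export
metabolic_water <- function(vo2_ml_h, rer, table = conversion_table()) {
  if (any(vo2_ml_h < 0)) stop("vo2 must be non-negative")
  vo2_ml_h * hygric_coef(rer, table)
}

#' Evaporative heat loss
#'
#' EHL = EWL x latent heat (default 2.4 J per mg H2O).
#'
#' @param ewl_mg_h evaporative water loss (mg h^-1, >= 0).
#' @param table a [conversion_table()].
#' @export
evaporative_heat <- function(ewl_mg_h, table = conversion_table()) {
  if (any(ewl_mg_h < 0)) stop("ewl must be non-negative")
  ewl_mg_h * table$latent_heat_J_mg
}

#' Wet and dry thermal conductance
#'
#' Mass-specific conductances (J g^-1 h^-1 degC^-1):
#' \deqn{C_{wet} = \frac{MHP/m}{T_b - T_a},\qquad
#'       C_{dry} = \frac{(MHP - EHL)/m}{T_b - T_a}.}
#' Above thermoneutrality EHL can exceed MHP, making C_dry negative; it is
#' reported with `defined = TRUE` but should be interpreted with care. When
#' the body-air gradient is below `gradient_floor_C` the ratio is numerically
#' meaningless and both values are returned as NA with `defined = FALSE`.
#'
#' @param mhp_J_h metabolic heat production (J h^-1).
#' @param ehl_J_h evaporative heat loss (J h^-1).
#' @param tb_C,ta_C body and ambient temperature (degC).
#' @param mass_g body mass (g).
#' @param gradient_floor_C minimum Tb - Ta (default 0.5).
#' @return list with `cwet`, `cdry` (J g^-1 h^-1 degC^-1) and `defined`.
#' @export
thermal_conductance <- function(mhp_J_h, ehl_J_h, tb_C, ta_C, mass_g,
                                gradient_floor_C = 0.5) {
  if (any(mass_g <= 0)) stop("mass must be positive")
  grad <- tb_C - ta_C
  defined <- grad >= gradient_floor_C
  cwet <- ifelse(defined, (mhp_J_h / mass_g) / grad, NA_real_)
  cdry <- ifelse(defined, ((mhp_J_h - ehl_J_h) / mass_g) / grad, NA_real_)
  list(cwet = cwet, cdry = cdry, defined = defined)
}

#' Relative water economy
#'
#' RWE = MWP/EWL. RWE = 1 marks the point of relative water economy (PRWE):
#' at ambient temperatures below it, metabolic water production exceeds
#' evaporative loss.
#'
#' @param mwp_mg_h metabolic water production (mg h^-1).
#' @param ewl_mg_h evaporative water loss (mg h^-1, > 0).
#' @export
relative_water_economy <- function(mwp_mg_h, ewl_mg_h) {
  if (any(ewl_mg_h <= 0)) stop("ewl must be positive to form RWE")
  mwp_mg_h / ewl_mg_h
}

#' Allometric scaling exponents for mass-independent values
#'
#' Marsupial exponents: metabolic rate 0.74, evaporative water loss 0.68,
#' wet thermal conductance 0.57. (Some sources print metabolic-rate units on
#' g^-0.75; the registry keeps 0.74 and both are configurable.)
#'
#' @param mr,ewl,cwet exponents.
#' @return named numeric vector.
#' @export
scaling_exponents <- function(mr = 0.74, ewl = 0.68, cwet = 0.57) {
  c(mr = mr, ewl = ewl, cwet = cwet)
}

#' Mass-independent (allometrically scaled) value
#'
#' value / mass^exponent, e.g. ml O2 g^-0.74 h^-1 for metabolic rate.
#'
#' @param value whole-animal value.
#' @param mass_g body mass (g, > 0).
#' @param exponent allometric exponent b.
#' @export
mass_independent <- function(value, mass_g, exponent) {
  if (any(mass_g <= 0)) stop("mass must be positive")
  value / mass_g^exponent
}

#' Assemble one trial's standard physiological record
#'
#' Combines the steady-window means with trial metadata into the standard
#' record: Ta, Tb, mass (mean of pre/post), VO2, VCO2, EWL, RER, MHP, MWP,
#' EHL, wet and dry conductance, RWE, and mass-independent VO2/EWL/C_wet.
#' Body temperature is the single post-trial cloacal measurement. Missing Tb
#' leaves the conductance fields NA with `conductance_defined = FALSE`; all
#' other fields are still populated.
#'
#' @param window a [find_steady_window()] result.
#' @param meta trial metadata list (from the trace).
#' @param table a [conversion_table()].
#' @param exponents a [scaling_exponents()] vector.
#' @param gradient_floor_C minimum Tb - Ta for conductance.
#' @return one-row data.frame (a `physio_record`).
#' @export
assemble_record <- function(window, meta, table = conversion_table(),
                            exponents = scaling_exponents(),
                            gradient_floor_C = 0.5) {
  stopifnot(inherits(window, "steady_window"))
  vo2 <- window$means[["vo2_ml_h"]]
  vco2 <- window$means[["vco2_ml_h"]]
  ewl <- window$means[["ewl_mg_h"]]
  mass <- mean(c(meta$mass_before_g, meta$mass_after_g))
  ta <- meta$ta_target_C
  tb <- meta$tb_final_C
  rer <- suppressWarnings(compute_rer(vo2, vco2))
  mhp <- metabolic_heat(vo2, rer, table)
  mwp <- metabolic_water(vo2, rer, table)
  ehl <- evaporative_heat(max(ewl, 0), table)
  if (!is.null(tb) && is.finite(tb)) {
    cond <- thermal_conductance(mhp, ehl, tb, ta, mass, gradient_floor_C)
  } else {
    tb <- NA_real_
    cond <- list(cwet = NA_real_, cdry = NA_real_, defined = FALSE)
  }
  rwe <- if (ewl > 0) relative_water_economy(mwp, ewl) else NA_real_
  data.frame(
    animal_id = meta$animal_id %||% NA_character_,
    population_id = meta$population_id %||% NA_character_,
    ta_C = ta, tb_C = tb, mass_g = mass,
    vo2_ml_h = vo2, vco2_ml_h = vco2, ewl_mg_h = ewl,
    rer = rer, mhp_J_h = mhp, mwp_mg_h = mwp, ehl_J_h = ehl,
    cwet_J_g_h_C = cond$cwet, cdry_J_g_h_C = cond$cdry, rwe = rwe,
    vo2_mi = mass_independent(vo2, mass, exponents[["mr"]]),
    ewl_mi = mass_independent(ewl, mass, exponents[["ewl"]]),
    cwet_mi = if (cond$defined)
      mass_independent(cond$cwet * mass, mass, exponents[["cwet"]]) else NA_real_,
    mr_exponent = exponents[["mr"]], ewl_exponent = exponents[["ewl"]],
    cwet_exponent = exponents[["cwet"]],
    steady = window$steady,
    conductance_defined = cond$defined,
    stringsAsFactors = FALSE
  )
}
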