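BASELINE_CHANNELS <- c("o2_frac", "co2_frac", "rh_pct")

#' Fit a linear baseline drift model
#'
#' Baselines of background O2, CO2 and RH are recorded for at least 20 min
#' before and after the animal is in the chamber. For each channel the model
#' anchors a straight line at the two baseline means (evaluated at the
#' midpoints of the two windows); evaluating it at any time gives the
#' drift-corrected incurrent reference at that moment.
#'
#' @param trace a calibrated [resp_trace()] with both baseline phases.
#' @param min_duration_s minimum acceptable baseline duration (default 1200 s
#'   = 20 min).
#' @return object of class `resp_baseline`: per channel pre/post means,
#'   midpoint times, slope per second, and baseline noise SD.
#' @export
fit_baseline <- function(trace, min_duration_s = 1200) {
  stopifnot(inherits(trace, "resp_trace"))
  d <- trace$data
  for (ph in c("baseline_pre", "baseline_post")) {
    if (!any(d$phase == ph)) stop("baseline phase missing: ", ph)
    dur <- phase_duration(trace, ph)
    if (dur < min_duration_s) {
      stop("phase ", ph, " lasts ", round(dur), " s, shorter than the ",
           min_duration_s, " s minimum")
    }
  }
  pre <- d[d$phase == "baseline_pre", ]
  post <- d[d$phase == "baseline_post", ]
  channels <- lapply(BASELINE_CHANNELS, function(ch) {
    pre_mean <- mean(pre[[ch]])
    post_mean <- mean(post[[ch]])
    t_pre <- mean(pre$time_s)
    t_post <- mean(post$time_s)
    list(channel = ch,
         pre_mean = pre_mean, post_mean = post_mean,
         t_pre = t_pre, t_post = t_post,
         slope = (post_mean - pre_mean) / (t_post - t_pre),
         noise_sd = stats::sd(c(pre[[ch]] - pre_mean, post[[ch]] - post_mean)))
  })
  names(channels) <- BASELINE_CHANNELS
  structure(list(channels = channels, min_duration_s = min_duration_s),
            class = "resp_baseline")
}

#' Evaluate the baseline drift line for a channel at given times
#'
#' @param baseline a [fit_baseline()] result.
#' @param channel one of `"o2_frac"`, `"co2_frac"`, `"rh_pct"`.
#' @param time_s numeric vector of times (s).
#' @return drift-corrected incurrent reference values.
#' @export
predict_baseline <- function(baseline, channel, time_s) {
  stopifnot(inherits(baseline, "resp_baseline"))
  ch <- baseline$channels[[channel]]
  if (is.null(ch)) stop("unknown baseline channel: ", channel)
  ch$pre_mean + ch$slope * (time_s - ch$t_pre)
}

#' Dry-nitrogen mass-balance inversion of flow-through respirometry
#'
#' With dry incurrent flow VI at STPD and dry gas fractions measured after
#' desiccation, nitrogen is conserved, so the dry excurrent flow is
#' \deqn{\dot V_{E,dry} = \dot V_I (1 - FiO_2 - FiCO_2)/(1 - FeO_2 - FeCO_2)}
#' and
#' \deqn{\dot VO_2 = \dot V_I FiO_2 - \dot V_{E,dry} FeO_2, \quad
#'       \dot VCO_2 = \dot V_{E,dry} FeCO_2 - \dot V_I FiCO_2.}
#' The algebra is exact; no respiratory-quotient approximation is used.
#' When the respiratory exchange ratio is 1, \eqn{\dot V_{E,dry} = \dot V_I}.
#'
#' @param fe_o2,fe_co2 dry excurrent fractions (dimensionless).
#' @param fi_o2,fi_co2 dry incurrent fractions (defaults: room air 0.2095 O2,
#'   0.0004 CO2).
#' @param flow_stpd_ml_min dry incurrent flow at STPD (ml min^-1).
#' @return data.frame with `vo2_ml_h`, `vco2_ml_h` (ml STPD h^-1) and
#'   `ve_dry_ml_min`. Negative computed rates are returned as-is (a baseline
#'   or calibration fault upstream), never silently clipped.
#' @examples
#' compute_gas_exchange(0.2065, 0.0034, flow_stpd_ml_min = 3000)
#' @export
compute_gas_exchange <- function(fe_o2, fe_co2, fi_o2 = 0.2095,
                                 fi_co2 = 0.0004, flow_stpd_ml_min) {
  if (any(flow_stpd_ml_min <= 0)) stop("flow must be positive")
  fr <- c(fe_o2, fe_co2, fi_o2, fi_co2)
  if (any(fr < 0 | fr >= 1)) stop("gas fractions must lie in [0, 1)")
  if (any(fe_o2 + fe_co2 >= 1)) stop("FeO2 + FeCO2 >= 1: no nitrogen balance possible")
  if (any(fi_o2 + fi_co2 >= 1)) stop("FiO2 + FiCO2 >= 1: no nitrogen balance possible")
  ve_dry <- flow_stpd_ml_min * (1 - fi_o2 - fi_co2) / (1 - fe_o2 - fe_co2)
  vo2 <- 60 * (flow_stpd_ml_min * fi_o2 - ve_dry * fe_o2)
  vco2 <- 60 * (ve_dry * fe_co2 - flow_stpd_ml_min * fi_co2)
  data.frame(vo2_ml_h = vo2, vco2_ml_h = vco2, ve_dry_ml_min = ve_dry)
}

#' Magnus saturation vapor pressure constants (kPa, dimensionless, degC)
#' @export
magnus_default <- function() c(a = 0.61094, b = 17.625, c = 243.04)

#' Saturation water vapor pressure (Magnus form)
#'
#' \deqn{P_{sat}(T) = a\,e^{bT/(T+c)}} in kPa with the configured constants.
#'
#' @param t_C air temperature (degC).
#' @param magnus constants `c(a, b, c)`; see [magnus_default()].
#' @return saturation vapor pressure (kPa).
#' @export
saturation_vp <- function(t_C, magnus = magnus_default()) {
  magnus[["a"]] * exp(magnus[["b"]] * t_C / (t_C + magnus[["c"]]))
}

# mg per mmol of water / ml STPD per mmol of ideal gas
WATER_MG_PER_MMOL <- 18.016
GAS_ML_PER_MMOL <- 22.414

#' Psychrometric evaporative water loss from excurrent humidity
#'
#' Incurrent air is dried, so all excurrent water vapor is evaporative loss.
#' Water vapor partial pressure is RH times the Magnus saturation pressure at
#' the probe temperature; the vapor volumetric flow then follows from the dry
#' excurrent flow by partial-pressure ratio, and mass via the molar volume:
#' \deqn{P_w = \frac{rh}{100} P_{sat}(T),\quad
#'   \dot V_w = \dot V_{E,dry}\frac{P_w}{BP - P_w},\quad
#'   EWL = 60\,\dot V_w \frac{18.016}{22.414}\ \mathrm{mg\,h^{-1}}.}
#'
#' @param rh_pct excurrent relative humidity (0-100).
#' @param t_probe_C humidity probe temperature (degC).
#' @param ve_dry_ml_min dry excurrent flow at STPD (ml min^-1).
#' @param bp_kPa barometric pressure (kPa).
#' @param magnus Magnus constants, see [magnus_default()].
#' @return evaporative water loss (mg H2O h^-1).
#' @examples
#' compute_ewl(25, 25, 2996.6)
#' @export
compute_ewl <- function(rh_pct, t_probe_C, ve_dry_ml_min,
                        bp_kPa = 101.325, magnus = magnus_default()) {
  if (any(rh_pct < 0 | rh_pct > 100)) stop("rh_pct must lie in [0, 100]")
  pw <- rh_pct / 100 * saturation_vp(t_probe_C, magnus)
  if (any(pw >= bp_kPa)) stop("water vapor pressure >= barometric pressure")
  vw <- ve_dry_ml_min * pw / (bp_kPa - pw)
  60 * vw * WATER_MG_PER_MMOL / GAS_ML_PER_MMOL
}

#' Baseline-correct a trace and invert it to gas-exchange rates
#'
#' For each animal-phase sample the incurrent reference composition is the
#' drift-corrected baseline value at that time and the excurrent composition
#' is the measured value; [compute_gas_exchange()] and [compute_ewl()] are
#' applied pointwise. Excurrent RH is corrected by subtracting the RH
#' baseline drift (background moisture), floored at 0.
#'
#' @param trace calibrated [resp_trace()].
#' @param baseline a [fit_baseline()] model for `trace`.
#' @param bp_kPa barometric pressure; defaults to the trace metadata.
#' @param magnus Magnus constants for [compute_ewl()].
#' @return a `gas_series` data.frame (`time_s`, `vo2_ml_h`, `vco2_ml_h`,
#'   `ewl_mg_h`, `ve_dry_ml_min`) over the animal phase, with the trace
#'   metadata attached as attribute `meta`.
#' @export
correct_series <- function(trace, baseline, bp_kPa = NULL,
                           magnus = magnus_default()) {
  stopifnot(inherits(trace, "resp_trace"), inherits(baseline, "resp_baseline"))
  d <- trace$data[trace$data$phase == "animal", ]
  if (nrow(d) == 0) stop("trace has no animal phase")
  bp <- bp_kPa %||% trace$meta$barometric_pressure_kPa %||% 101.325
  fi_o2 <- predict_baseline(baseline, "o2_frac", d$time_s)
  fi_co2 <- pmax(predict_baseline(baseline, "co2_frac", d$time_s), 0)
  gx <- compute_gas_exchange(d$o2_frac, d$co2_frac, fi_o2, fi_co2,
                             d$flow_stpd_ml_min)
  rh_corr <- pmin(pmax(d$rh_pct - predict_baseline(baseline, "rh_pct", d$time_s), 0), 100)
  ewl <- compute_ewl(rh_corr, d$t_probe_C, gx$ve_dry_ml_min, bp, magnus)
  out <- data.frame(time_s = d$time_s, vo2_ml_h = gx$vo2_ml_h,
                    vco2_ml_h = gx$vco2_ml_h, ewl_mg_h = ewl,
                    ve_dry_ml_min = gx$ve_dry_ml_min)
  attr(out, "meta") <- trace$meta
  class(out) <- c("gas_series", "data.frame")
  out
}

#' Find the steady-and-minimal analysis window
#'
#' Resting rates are taken over a period of at least `min_duration_s` when
#' values are steady and minimal. Candidate windows start at every sample and
#' take every admissible length; a window qualifies when its VO2 coefficient
#' of variation is at most `cv_max`, the absolute least-squares VO2 slope is
#' at most `slope_max_frac_h` of the window mean per hour, and it contains no
#' non-positive VO2 samples. Among qualifying windows the one with minimal
#' mean VO2 wins; ties (relative difference below 1e-9) go to the earliest
#' start, then the longest window. If no window qualifies, the minimal-CV
#' window is returned flagged `steady = FALSE`.
#'
#' Stability is judged on VO2 only; VCO2 and EWL means are reported over the
#' same window.
#'
#' @param series a `gas_series` from [correct_series()].
#' @param min_duration_s minimum window length (s); default 1200 (20 min).
#' @param cv_max maximum VO2 coefficient of variation (default 0.10).
#' @param slope_max_frac_h maximum |slope| as a fraction of the window mean
#'   per hour (default 0.05).
#' @param min_start_s earliest admissible window start, in seconds from the
#'   first animal-phase sample; used to discard the chamber washout
#'   equilibration (default 0).
#' @return object of class `steady_window`: `start_s`, `end_s` (half-open),
#'   per-channel means, `cv`, `slope_ml_h_per_h`, and logical `steady`.
#' @export
find_steady_window <- function(series, min_duration_s = 1200, cv_max = 0.10,
                               slope_max_frac_h = 0.05, min_start_s = 0) {
  stopifnot(inherits(series, "data.frame"))
  t <- series$time_s
  y <- series$vo2_ml_h
  n <- length(y)
  if (n < 2) stop("series too short")
  t0 <- t[1]
  dur_total <- t[n] - t0
  if (dur_total < min_duration_s) {
    stop("animal phase (", round(dur_total), " s) shorter than the minimum window (",
         min_duration_s, " s)")
  }
  first_start <- match(TRUE, t - t0 >= min_start_s)
  if (is.na(first_start) || t[n] - t[first_start] < min_duration_s) {
    first_start <- 1L  # washout discard would leave no admissible window
  }

  # prefix sums for O(1) window statistics
  cy <- c(0, cumsum(y))
  cy2 <- c(0, cumsum(y * y))
  ct <- c(0, cumsum(t))
  ct2 <- c(0, cumsum(t * t))
  cty <- c(0, cumsum(t * y))
  cpos <- c(0, cumsum(y <= 0))

  best <- NULL        # qualifying: minimal mean
  best_cv <- NULL     # fallback: minimal CV
  for (s in first_start:(n - 1)) {
    # smallest end index giving duration >= min_duration_s (end inclusive)
    e_min <- s + match(TRUE, t[(s + 1):n] - t[s] >= min_duration_s)
    if (is.na(e_min) || e_min > n) break
    e <- e_min:n
    k <- e - s + 1
    sum_y <- cy[e + 1] - cy[s]
    sum_y2 <- cy2[e + 1] - cy2[s]
    mu <- sum_y / k
    varr <- pmax(sum_y2 / k - mu * mu, 0)
    cv <- sqrt(varr * k / pmax(k - 1, 1)) / mu
    sum_t <- ct[e + 1] - ct[s]
    sum_t2 <- ct2[e + 1] - ct2[s]
    sum_ty <- cty[e + 1] - cty[s]
    sxx <- sum_t2 - sum_t * sum_t / k
    sxy <- sum_ty - sum_t * sum_y / k
    slope <- sxy / sxx                      # ml h^-1 per second
    slope_frac_h <- abs(slope) * 3600 / mu  # fraction of mean per hour
    clean <- (cpos[e + 1] - cpos[s]) == 0
    ok <- clean & mu > 0 & cv <= cv_max & slope_frac_h <= slope_max_frac_h

    if (any(ok)) {
      idx <- which(ok)
      mu_ok <- mu[idx]
      best_i <- idx[order(mu_ok, -k[idx])[1]]
      cand <- list(s = s, e = e[best_i], mean = mu[best_i], cv = cv[best_i],
                   slope = slope[best_i])
      if (is.null(best) || better_window(cand, best)) best <- cand
    }
    cv_ok <- which(clean & mu > 0)
    if (length(cv_ok) > 0) {
      i <- cv_ok[order(cv[cv_ok], -k[cv_ok])[1]]
      cand <- list(s = s, e = e[i], mean = mu[i], cv = cv[i], slope = slope[i])
      if (is.null(best_cv) || cand$cv < best_cv$cv - 1e-15) best_cv <- cand
    }
  }
  steady <- !is.null(best)
  if (!steady) {
    if (is.null(best_cv)) stop("no admissible window (all windows contain non-positive VO2)")
    best <- best_cv
  }
  window_result(series, best, steady)
}

# minimal mean, ties (1e-9 relative) -> earliest start -> longest
better_window <- function(a, b) {
  tol <- 1e-9 * max(abs(a$mean), abs(b$mean), 1e-300)
  if (a$mean < b$mean - tol) return(TRUE)
  if (a$mean > b$mean + tol) return(FALSE)
  if (a$s != b$s) return(a$s < b$s)
  (a$e - a$s) > (b$e - b$s)
}

window_result <- function(series, w, steady) {
  idx <- w$s:w$e
  dt <- stats::median(diff(series$time_s))
  structure(list(
    start_s = series$time_s[w$s],
    end_s = series$time_s[w$e] + dt,
    n = length(idx),
    means = c(vo2_ml_h = mean(series$vo2_ml_h[idx]),
              vco2_ml_h = mean(series$vco2_ml_h[idx]),
              ewl_mg_h = mean(series$ewl_mg_h[idx])),
    cv = w$cv,
    slope_ml_h_per_h = w$slope * 3600,
    steady = steady
  ), class = "steady_window")
}

#' @export
print.steady_window <- function(x, ...) {
  cat(sprintf("<steady_window> [%.0f, %.0f) s (%d samples)%s\n", x$start_s,
              x$end_s, x$n, if (x$steady) "" else "  ** NOT steady **"))
  cat(sprintf("  VO2 %.1f ml/h (CV %.3f, slope %.2f ml/h per h), VCO2 %.1f ml/h, EWL %.1f mg/h\n",
              x$means["vo2_ml_h"], x$cv, x$slope_ml_h_per_h,
              x$means["vco2_ml_h"], x$means["ewl_mg_h"]))
  invisible(x)
}
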