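#' Two-point instrument calibration model
#'
#' Gas analysers are spanned with a zero gas (nitrogen, 0% O2 and CO2) and a
#' span gas (room air 20.95% O2; a precision CO2 mix, e.g. 0.53%); the
#' humidity probe with two points (1% RH over desiccant, 100% RH saturated);
#' the mass flowmeter with a multiplicative STPD correction. Each gas/RH
#' channel is an affine map fixed by (raw reading at zero/low point, raw
#' reading at span/high point) and the true values at those points.
#'
#' @param o2,co2 numeric `c(raw_zero, raw_span, span_value)`; the zero point
#'   maps to 0. E.g. `c(0.001, 0.995, 0.2095)` maps raw 0.001 -> 0 and raw
#'   0.995 -> 0.2095.
#' @param rh numeric `c(raw_low, raw_high, low_value, high_value)`; defaults
#'   map the two readings to 1% and 100% RH.
#' @param flow_stpd_factor multiplier taking the recorded flow to STPD.
#' @return object of class `resp_calibration`.
#' @examples
#' cal <- calibration_model(o2 = c(0.01, 0.99, 0.2095))
#' @export
calibration_model <- function(o2 = c(0, 0.2095, 0.2095),
                              co2 = c(0, 0.0053, 0.0053),
                              rh = c(1, 100, 1, 100),
                              flow_stpd_factor = 1) {
  check_span <- function(x, name) {
    if (x[2] <= x[1]) {
      stop("calibration span for ", name,
           " must have span reading strictly greater than zero reading")
    }
    if (x[3] <= 0) stop("span value for ", name, " must be positive")
  }
  check_span(o2, "o2")
  check_span(co2, "co2")
  if (rh[2] <= rh[1]) stop("rh span readings must be increasing")
  if (flow_stpd_factor <= 0) stop("flow_stpd_factor must be positive")
  structure(list(o2 = o2, co2 = co2, rh = rh,
                 flow_stpd_factor = flow_stpd_factor),
            class = "resp_calibration")
}

#' Identity calibration (already-calibrated trace)
#' @return a `resp_calibration` that leaves any trace unchanged.
#' @export
identity_calibration <- function() calibration_model()

# affine map through two points
two_point_map <- function(raw, raw_lo, raw_hi, val_lo, val_hi) {
  val_lo + (raw - raw_lo) * (val_hi - val_lo) / (raw_hi - raw_lo)
}

#' Apply an instrument calibration to a trace
#'
#' Maps each gas channel through its two-point line (zero reading -> 0, span
#' reading -> span value), the RH channel through its two-point line, and
#' multiplies the flow channel by the STPD factor. Marks the trace metadata
#' `calibrated = "yes"`.
#'
#' @param trace a [resp_trace()].
#' @param cal a [calibration_model()].
#' @return calibrated [resp_trace()].
#' @export
apply_calibration <- function(trace, cal) {
  stopifnot(inherits(trace, "resp_trace"), inherits(cal, "resp_calibration"))
  d <- trace$data
  d$o2_frac <- two_point_map(d$o2_frac, cal$o2[1], cal$o2[2], 0, cal$o2[3])
  d$co2_frac <- two_point_map(d$co2_frac, cal$co2[1], cal$co2[2], 0, cal$co2[3])
  d$rh_pct <- two_point_map(d$rh_pct, cal$rh[1], cal$rh[2], cal$rh[3], cal$rh[4])
  d$flow_stpd_ml_min <- d$flow_stpd_ml_min * cal$flow_stpd_factor
  meta <- trace$meta
  meta$calibrated <- "yes"
  resp_trace(d, meta, validate = FALSE)
}
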