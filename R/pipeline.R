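#' Pipeline configuration
#'
#' Bundles every tunable of the trace-to-comparison workflow with documented
#' defaults. Serializes to YAML with [write_config()] / [read_config()]
#' (parse-serialize round trip is the identity).
#'
#' @param fi_o2,fi_co2 incurrent dry reference composition (room air).
#' @param bp_kPa barometric pressure fallback when a trace lacks it.
#' @param baseline_min_s minimum baseline duration (s).
#' @param window_min_s minimum steady-window duration (s).
#' @param cv_max maximum VO2 coefficient of variation within a window.
#' @param slope_max_frac_h maximum |window slope| as fraction of mean per h.
#' @param equilibration_tau chamber time constants (volume/flow) discarded at
#'   the start of the animal phase before window search.
#' @param oxycal,hygric,latent_heat_J_mg conversion-table knobs, see
#'   [conversion_table()].
#' @param exponents allometric exponents, see [scaling_exponents()].
#' @param thermoneutral_ta_C,thermoneutral_window_C Ta window defining
#'   standard (basal) records, default 26 +/- 1 degC.
#' @param alpha significance level for ANOVA/SNK.
#' @param reference_population reference level for location contrasts (NULL:
#'   first population alphabetically).
#' @param magnus Magnus vapor-pressure constants.
#' @param gradient_floor_C minimum Tb - Ta for conductance.
#' @param seed default seed for simulation entry points.
#' @return nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(fi_o2 = 0.2095, fi_co2 = 0.0004,
                            bp_kPa = 101.325,
                            baseline_min_s = 1200, window_min_s = 1200,
                            cv_max = 0.10, slope_max_frac_h = 0.05,
                            equilibration_tau = 8,
                            oxycal = c(0.71, 19.6, 1.00, 21.1),
                            hygric = c(0.71, 0.53, 1.00, 0.67),
                            latent_heat_J_mg = 2.4,
                            exponents = scaling_exponents(),
                            thermoneutral_ta_C = 26,
                            thermoneutral_window_C = 1,
                            alpha = 0.05,
                            reference_population = NULL,
                            magnus = magnus_default(),
                            gradient_floor_C = 0.5,
                            seed = 1) {
  structure(list(
    gas = list(fi_o2 = fi_o2, fi_co2 = fi_co2, bp_kPa = bp_kPa),
    baseline = list(min_duration_s = baseline_min_s),
    window = list(min_duration_s = window_min_s, cv_max = cv_max,
                  slope_max_frac_h = slope_max_frac_h,
                  equilibration_tau = equilibration_tau),
    conversion = list(oxycal = oxycal, hygric = hygric,
                      latent_heat_J_mg = latent_heat_J_mg),
    exponents = as.list(exponents),
    thermoneutral = list(ta_C = thermoneutral_ta_C,
                         window_C = thermoneutral_window_C),
    stats = list(alpha = alpha, reference_population = reference_population),
    magnus = as.list(magnus),
    gradient_floor_C = gradient_floor_C,
    seed = seed
  ), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  structure(yaml::read_yaml(path), class = "pipeline_config")
}

config_table <- function(config) {
  conversion_table(oxycal = as.numeric(config$conversion$oxycal),
                   hygric = as.numeric(config$conversion$hygric),
                   latent_heat_J_mg = config$conversion$latent_heat_J_mg)
}

config_exponents <- function(config) {
  scaling_exponents(mr = config$exponents$mr, ewl = config$exponents$ewl,
                    cwet = config$exponents$cwet)
}

#' Process traces into a standard physiological record table
#'
#' For each trace: fit the baseline drift model, baseline-correct and invert
#' to gas-exchange rates, discard the chamber-washout equilibration
#' (`equilibration_tau` time constants, with the time constant computed from
#' the chamber volume and flow), locate the steady-and-minimal window, and
#' assemble the standard record. Per-trace failures are collected, not
#' fatal: the returned table carries an `errors` attribute (data.frame of
#' trace name and message).
#'
#' @param traces a named list of [resp_trace()] objects, a character vector
#'   of trace CSV paths, or a directory containing trace CSVs.
#' @param config a [pipeline_config()].
#' @param cal optional [calibration_model()] applied to every trace first.
#' @return data.frame of records, one row per successfully processed trace.
#' @export
process_traces <- function(traces, config = pipeline_config(), cal = NULL) {
  if (is.character(traces)) {
    if (length(traces) == 1 && dir.exists(traces)) {
      traces <- list.files(traces, pattern = "\\.csv$", full.names = TRUE)
      traces <- traces[basename(traces) != "truth.csv"]
    }
    nms <- sub("\\.csv$", "", basename(traces))
    paths <- traces
    loader <- function(i) read_trace(paths[i])
    n <- length(paths)
  } else {
    stopifnot(is.list(traces))
    nms <- names(traces) %||% as.character(seq_along(traces))
    loader <- function(i) traces[[i]]
    n <- length(traces)
  }
  table <- config_table(config)
  exps <- config_exponents(config)
  magnus <- unlist(config$magnus)
  records <- vector("list", n)
  errors <- list()
  for (i in seq_len(n)) {
    rec <- tryCatch({
      trace <- loader(i)
      if (!is.null(cal)) trace <- apply_calibration(trace, cal)
      record_from_trace(trace, config, table, exps, magnus)
    }, error = function(e) e)
    if (inherits(rec, "error")) {
      errors[[length(errors) + 1L]] <- data.frame(
        trace = nms[i], message = conditionMessage(rec),
        stringsAsFactors = FALSE)
    } else {
      records[[i]] <- rec
    }
  }
  out <- do.call(rbind, records[!vapply(records, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame()
  }
  rownames(out) <- NULL
  attr(out, "errors") <- if (length(errors)) do.call(rbind, errors) else
    data.frame(trace = character(), message = character())
  out
}

record_from_trace <- function(trace, config, table, exps, magnus) {
  baseline <- fit_baseline(trace, min_duration_s = config$baseline$min_duration_s)
  series <- correct_series(trace, baseline,
                           bp_kPa = trace$meta$barometric_pressure_kPa %||%
                             config$gas$bp_kPa,
                           magnus = magnus)
  vol <- trace$meta$chamber_volume_ml
  flow <- stats::median(series$ve_dry_ml_min)
  min_start <- if (!is.null(vol) && is.finite(vol)) {
    config$window$equilibration_tau * 60 * vol / flow
  } else 0
  window <- find_steady_window(series,
                               min_duration_s = config$window$min_duration_s,
                               cv_max = config$window$cv_max,
                               slope_max_frac_h = config$window$slope_max_frac_h,
                               min_start_s = min_start)
  assemble_record(window, trace$meta, table = table, exponents = exps,
                  gradient_floor_C = config$gradient_floor_C)
}

#' Fit thermal responses and compare populations
#'
#' The full comparison stage: per population and variable, the quadratic
#' thermal-response mixed model with the boundary-corrected likelihood ratio
#' test of the individual random effect; across populations, the joint mixed
#' model with population and Ta-by-population effects (contrasts against the
#' reference population); PRWE per population from the fitted RWE response;
#' and one-way ANOVA with SNK letters on the standard (thermoneutral-window)
#' records. With a single population the between-location sections are
#' skipped with a notice.
#'
#' @param records record table from [process_traces()] (or a truth table).
#' @param config a [pipeline_config()].
#' @param variables named character vector of response columns to analyse.
#' @return list of class `population_comparison` with elements `fits`
#'   (per variable, per population), `lrt`, `locations` (per variable),
#'   `prwe` (data.frame), `snk` (per variable), `notes`.
#' @export
compare_populations <- function(records, config = pipeline_config(),
                                variables = c(tb = "tb_C", mr = "vo2_mi",
                                              ewl = "ewl_mi",
                                              cwet = "cwet_mi", rwe = "rwe")) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  pops <- sort(unique(records$population_id))
  reference <- config$stats$reference_population %||% pops[1]
  notes <- character()
  fits <- list()
  lrt <- list()
  for (v in variables) {
    fits[[v]] <- list()
    lrt[[v]] <- list()
    for (p in pops) {
      f <- tryCatch(fit_thermal_response(records, v, population = p),
                    error = function(e) e)
      if (inherits(f, "error")) {
        notes <- c(notes, sprintf("fit %s/%s failed: %s", v, p,
                                  conditionMessage(f)))
        next
      }
      fits[[v]][[p]] <- f
      lrt[[v]][[p]] <- lrt_random_effect(f)
    }
  }
  locations <- list()
  if (length(pops) >= 2) {
    for (v in variables) {
      lc <- tryCatch(compare_locations(records, v, reference),
                     error = function(e) e)
      if (inherits(lc, "error")) {
        notes <- c(notes, sprintf("location comparison for %s failed: %s", v,
                                  conditionMessage(lc)))
      } else {
        locations[[v]] <- lc
      }
    }
  } else {
    notes <- c(notes, "single population: between-location comparison skipped")
  }
  prwe_rows <- lapply(pops, function(p) {
    est <- tryCatch(estimate_prwe(records, population = p),
                    error = function(e) NULL)
    if (is.null(est)) return(NULL)
    data.frame(population_id = p, prwe_C = est$prwe_C,
               extrapolated = est$extrapolated, status = est$status,
               stringsAsFactors = FALSE)
  })
  prwe <- do.call(rbind, prwe_rows)
  tnz <- config$thermoneutral
  std <- records[abs(records$ta_C - tnz$ta_C) <= tnz$window_C, ]
  snk <- list()
  if (length(pops) >= 2 && nrow(std) > 0) {
    for (v in variables) {
      res <- tryCatch(anova_snk(std, v, alpha = config$stats$alpha),
                      error = function(e) e)
      if (inherits(res, "error")) {
        notes <- c(notes, sprintf("ANOVA/SNK for %s failed: %s", v,
                                  conditionMessage(res)))
      } else {
        snk[[v]] <- res
      }
    }
  }
  structure(list(fits = fits, lrt = lrt, locations = locations, prwe = prwe,
                 snk = snk, reference = reference, variables = variables,
                 populations = pops, notes = notes),
            class = "population_comparison")
}

#' @export
print.population_comparison <- function(x, ...) {
  cat("<population_comparison> populations:",
      paste(x$populations, collapse = ", "),
      "| reference:", x$reference, "\n")
  if (!is.null(x$prwe)) {
    cat("PRWE (degC):\n")
    print(x$prwe, row.names = FALSE)
  }
  for (v in names(x$snk)) {
    print(x$snk[[v]])
  }
  for (n in x$notes) cat("note:", n, "\n")
  invisible(x)
}

#' Write a population comparison as JSON and a text report
#'
#' @param comparison a [compare_populations()] result.
#' @param dir output directory (created if needed); writes
#'   `comparison.json` and `comparison.txt`.
#' @return the directory, invisibly.
#' @export
write_comparison_report <- function(comparison, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  js <- list(
    reference = comparison$reference,
    populations = comparison$populations,
    prwe = comparison$prwe,
    fits = lapply(comparison$fits, function(by_pop)
      lapply(by_pop, function(f) list(
        population = f$population_id, variable = f$variable,
        coefficients = as.list(f$coefficients), se = as.list(f$se),
        var_individual = f$var_individual, var_residual = f$var_residual,
        coding = as.list(f$coding), n_individuals = f$n_individuals,
        n_obs = f$n_obs, boundary = f$boundary))),
    lrt = lapply(comparison$lrt, function(by_pop)
      lapply(by_pop, function(l) l[c("statistic", "p")])),
    locations = lapply(comparison$locations, function(lc) list(
      variable = lc$variable, wald = lc$wald, contrasts = lc$contrasts,
      lrt_random = lc$lrt_random)),
    snk = lapply(comparison$snk, function(s) list(
      variable = s$variable, F = s$F, df = s$df, p = s$p,
      groups = s$groups)),
    notes = comparison$notes
  )
  jsonlite::write_json(js, file.path(dir, "comparison.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  txt <- utils::capture.output(print(comparison))
  for (v in names(comparison$locations)) {
    txt <- c(txt, "", utils::capture.output(print(comparison$locations[[v]])))
  }
  writeLines(txt, file.path(dir, "comparison.txt"))
  invisible(dir)
}

#' Simulate the default cohort (convenience wrapper)
#'
#' @param seed integer seed.
#' @param chamber a [chamber_config()].
#' @param scenarios list of scenarios (default presets).
#' @param out_dir optional output directory for CSVs.
#' @return see [generate_cohort()].
#' @export
simulate_cohort <- function(seed = 1, chamber = chamber_config(),
                            scenarios = preset_scenarios(), out_dir = NULL) {
  generate_cohort(scenarios = scenarios, chamber = chamber, seed = seed,
                  out_dir = out_dir)
}
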