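TRACE_CHANNELS <- c("time_s", "o2_frac", "co2_frac", "rh_pct", "t_probe_C",
                    "flow_stpd_ml_min", "phase")
TRACE_PHASES <- c("baseline_pre", "animal", "baseline_post")

META_NUMERIC <- c("mass_before_g", "mass_after_g", "tb_final_C", "ta_target_C",
                  "chamber_volume_ml", "barometric_pressure_kPa",
                  "sample_interval_s")

#' Construct a respirometry chamber trace
#'
#' A `resp_trace` holds one trial's multichannel time series (dry excurrent
#' O2 and CO2 fractions, excurrent relative humidity, probe temperature,
#' STPD mass-flow rate) with a phase label per sample
#' (`baseline_pre`, `animal`, `baseline_post`) and per-trial metadata.
#'
#' Gas fractions are stored dimensionless (room air O2 = 0.2095, not 20.95);
#' [read_trace()] converts from percent when the file header declares
#' `fraction_units=percent`.
#'
#' @param data data.frame with columns `time_s`, `o2_frac`, `co2_frac`,
#'   `rh_pct`, `t_probe_C`, `flow_stpd_ml_min`, `phase`.
#' @param meta named list of trial metadata. Recognized keys:
#'   `animal_id`, `population_id`, `species`, `mass_before_g`, `mass_after_g`,
#'   `tb_final_C`, `ta_target_C`, `chamber_volume_ml`,
#'   `barometric_pressure_kPa`, `sample_interval_s`. When
#'   `barometric_pressure_kPa` is absent it defaults to 101.325 with a warning.
#' @param validate check structural invariants (time strictly increasing,
#'   phase order, positive flow) and error on violation.
#' @return object of class `resp_trace`.
#' @seealso [read_trace()], [write_trace()], [validate_trace()]
#' @export
resp_trace <- function(data, meta = list(), validate = TRUE) {
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(TRACE_CHANNELS, names(data))
  if (length(missing_cols) > 0) {
    stop("trace data is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  data <- as.data.frame(data)[TRACE_CHANNELS]
  data$phase <- as.character(data$phase)
  if (is.null(meta$barometric_pressure_kPa)) {
    warning("barometric_pressure_kPa absent from metadata; defaulting to 101.325 kPa")
    meta$barometric_pressure_kPa <- 101.325
  }
  x <- structure(list(data = data, meta = meta), class = "resp_trace")
  if (validate) {
    stop_on_structural_faults(x)
  }
  x
}

# structural invariants that make a trace unusable (distinct from the
# advisory physical-range findings of validate_trace)
stop_on_structural_faults <- function(trace) {
  d <- trace$data
  bad_phase <- which(!d$phase %in% TRACE_PHASES)
  if (length(bad_phase) > 0) {
    stop("unknown phase label '", d$phase[bad_phase[1]], "' at row ", bad_phase[1])
  }
  dt <- diff(d$time_s)
  bad_t <- which(dt <= 0)
  if (length(bad_t) > 0) {
    stop("time not strictly increasing at row ", bad_t[1] + 1L)
  }
  ord <- match(unique(d$phase), TRACE_PHASES)
  if (is.unsorted(ord)) {
    stop("phases out of order: expected baseline_pre, animal, baseline_post")
  }
  runs <- rle(d$phase)
  if (any(duplicated(runs$values))) {
    stop("phase blocks must be contiguous (a phase label recurs after ending)")
  }
  if (any(d$flow_stpd_ml_min <= 0)) {
    stop("flow_stpd_ml_min must be positive at row ",
         which(d$flow_stpd_ml_min <= 0)[1])
  }
  invisible(trace)
}

#' @export
print.resp_trace <- function(x, ...) {
  d <- x$data
  cat("<resp_trace> ", nrow(d), " samples, ",
      sprintf("%.1f", diff(range(d$time_s)) / 60), " min\n", sep = "")
  tab <- table(factor(d$phase, levels = TRACE_PHASES))
  cat("  phases: ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n", sep = "")
  id <- x$meta$animal_id
  if (!is.null(id)) {
    cat("  animal ", id, " (", x$meta$population_id %||% "?", "), Ta target ",
        x$meta$ta_target_C %||% NA, " C\n", sep = "")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a trace to the canonical CSV format
#'
#' One CSV per trial: metadata as `# key=value` comment lines, then a header
#' row and the seven channel columns. Numeric fields are written with full
#' precision (17 significant digits) so a write/read round trip is exact.
#'
#' @param trace a [resp_trace()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "resp_trace"))
  meta <- trace$meta
  con <- file(path, "w")
  on.exit(close(con))
  for (key in names(meta)) {
    writeLines(sprintf("# %s=%s", key, format(meta[[key]], digits = 17)), con)
  }
  d <- trace$data
  num <- TRACE_CHANNELS[TRACE_CHANNELS != "phase"]
  out <- d
  for (v in num) out[[v]] <- formatC(d[[v]], digits = 17, format = "g")
  writeLines(paste(TRACE_CHANNELS, collapse = ","), con)
  writeLines(do.call(paste, c(out[TRACE_CHANNELS], sep = ",")), con)
  invisible(path)
}

#' Read a trace from the canonical CSV format
#'
#' Parses `# key=value` header metadata, then the channel table. Column names
#' can be remapped from a foreign dialect via `schema` (a named character
#' vector `c(canonical = "file_column")`). If the header carries
#' `fraction_units=percent`, O2/CO2 fractions are divided by 100 on read.
#'
#' @param path CSV file path.
#' @param schema optional named character vector mapping canonical column
#'   names to the file's column names.
#' @return a [resp_trace()].
#' @export
read_trace <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("trace file does not exist: ", path)
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  meta <- list()
  for (ln in lines[hdr]) {
    kv <- sub("^#\\s*", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq < 0) next
    key <- trimws(substr(kv, 1, eq - 1))
    val <- trimws(substr(kv, eq + 1, nchar(kv)))
    if (key %in% META_NUMERIC) {
      meta[[key]] <- as.numeric(val)
    } else {
      meta[[key]] <- val
    }
  }
  body <- lines[!hdr]
  if (length(body) < 2) stop("trace file has no data rows: ", path)
  d <- utils::read.csv(text = body, stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    for (canonical in names(schema)) {
      if (!schema[[canonical]] %in% names(d)) {
        stop("schema column '", schema[[canonical]], "' not found in ", path)
      }
      names(d)[names(d) == schema[[canonical]]] <- canonical
    }
  }
  missing_cols <- setdiff(TRACE_CHANNELS, names(d))
  if (length(missing_cols) > 0) {
    stop("trace file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (v in TRACE_CHANNELS[TRACE_CHANNELS != "phase"]) {
    d[[v]] <- as.numeric(d[[v]])
  }
  units <- meta$fraction_units %||% "fraction"
  if (identical(units, "percent")) {
    d$o2_frac <- d$o2_frac / 100
    d$co2_frac <- d$co2_frac / 100
    meta$fraction_units <- "fraction"
  }
  resp_trace(d, meta)
}

#' Default physical-range rules for trace validation
#'
#' @param o2_range,co2_range plausible dry-fraction ranges after calibration.
#' @param rh_range relative-humidity range (percent).
#' @param min_animal_s minimum animal-phase duration (s) before a warning.
#' @param min_baseline_s minimum baseline duration (s) before a warning.
#' @return named list of rules for [validate_trace()].
#' @export
trace_rules <- function(o2_range = c(0, 0.25), co2_range = c(0, 0.06),
                        rh_range = c(0, 100), min_animal_s = 1200,
                        min_baseline_s = 1200) {
  list(o2_range = o2_range, co2_range = co2_range, rh_range = rh_range,
       min_animal_s = min_animal_s, min_baseline_s = min_baseline_s)
}

#' Validate a trace against physical-range and duration rules
#'
#' Returns findings rather than throwing: each finding has a severity
#' (`"error"` for range violations, `"warning"` for short phases), the
#' channel, the first offending row (NA for phase-level findings) and a
#' message. An empty data.frame means the trace passes every check.
#'
#' @param trace a [resp_trace()].
#' @param rules rule set from [trace_rules()].
#' @return data.frame with columns severity, channel, row, message.
#' @export
validate_trace <- function(trace, rules = trace_rules()) {
  stopifnot(inherits(trace, "resp_trace"))
  d <- trace$data
  findings <- list()
  add <- function(severity, channel, row, message) {
    findings[[length(findings) + 1L]] <<- data.frame(
      severity = severity, channel = channel, row = row, message = message,
      stringsAsFactors = FALSE)
  }
  range_check <- function(channel, rng) {
    bad <- which(d[[channel]] < rng[1] | d[[channel]] > rng[2])
    if (length(bad) > 0) {
      add("error", channel, bad[1],
          sprintf("%s outside [%g, %g] at %d row(s), first at row %d",
                  channel, rng[1], rng[2], length(bad), bad[1]))
    }
  }
  range_check("o2_frac", rules$o2_range)
  range_check("co2_frac", rules$co2_range)
  range_check("rh_pct", rules$rh_range)
  for (ph in TRACE_PHASES) {
    idx <- d$phase == ph
    if (!any(idx)) {
      add("error", "phase", NA_integer_, sprintf("phase %s absent", ph))
      next
    }
    dur <- phase_duration(trace, ph)
    min_dur <- if (ph == "animal") rules$min_animal_s else rules$min_baseline_s
    if (dur < min_dur) {
      add("warning", "phase", which(idx)[1],
          sprintf("phase %s lasts %.0f s, shorter than %g s", ph, dur, min_dur))
    }
  }
  if (length(findings) == 0) {
    return(data.frame(severity = character(), channel = character(),
                      row = integer(), message = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, findings)
}

# duration of a phase, counting each sample as one sampling interval
phase_duration <- function(trace, phase) {
  d <- trace$data
  idx <- which(d$phase == phase)
  if (length(idx) == 0) return(0)
  dt <- trace$meta$sample_interval_s %||% stats::median(diff(d$time_s))
  length(idx) * dt
}
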