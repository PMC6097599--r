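# Independent oracles and small simulators used across the test files.

# Exhaustive brute-force steady-window search: enumerates every (start, end)
# pair, computes statistics with plain mean/sd/cov on the raw subvectors, and
# applies the published policy (minimal mean among qualifying windows,
# near-ties (1e-9 relative) to earliest start then longest; fallback to the
# minimal-CV window flagged non-steady).
window_oracle <- function(series, min_duration_s = 1200, cv_max = 0.10,
                          slope_max_frac_h = 0.05, min_start_s = 0) {
  t <- series$time_s
  y <- series$vo2_ml_h
  n <- length(y)
  t0 <- t[1]
  first_start <- match(TRUE, t - t0 >= min_start_s)
  if (is.na(first_start) || t[n] - t[first_start] < min_duration_s) {
    first_start <- 1L
  }
  rows <- list()
  for (s in first_start:(n - 1)) {
    for (e in (s + 1):n) {
      if (t[e] - t[s] < min_duration_s) next
      yy <- y[s:e]
      if (any(yy <= 0)) next
      tt <- t[s:e]
      mu <- mean(yy)
      if (mu <= 0) next
      cv <- stats::sd(yy) / mu
      slope <- stats::cov(tt, yy) / stats::var(tt)
      rows[[length(rows) + 1L]] <- c(s = s, e = e, mean = mu, cv = cv,
                                     ok = cv <= cv_max &&
                                       abs(slope) * 3600 / mu <= slope_max_frac_h)
    }
  }
  if (length(rows) == 0) return(NULL)
  w <- as.data.frame(do.call(rbind, rows))
  pick <- function(d, crit) {
    m0 <- min(d[[crit]])
    tol <- if (crit == "mean") 1e-9 * max(abs(m0), 1e-300) else 1e-15
    d <- d[d[[crit]] <= m0 + tol, ]
    d <- d[d$s == min(d$s), ]
    d[which.max(d$e - d$s), ]
  }
  q <- w[w$ok == 1, ]
  if (nrow(q) > 0) {
    sel <- pick(q, "mean")
    steady <- TRUE
  } else {
    sel <- pick(w, "cv")
    steady <- FALSE
  }
  dt <- stats::median(diff(t))
  list(start_s = t[sel$s], end_s = t[sel$e] + dt, steady = steady,
       mean = sel$mean)
}

# gas series wrapper for raw vo2 vectors (other channels unused by the search)
as_gas_series <- function(vo2, dt = 10) {
  structure(data.frame(time_s = dt * seq_along(vo2), vo2_ml_h = vo2,
                       vco2_ml_h = vo2 * 0.85, ewl_mg_h = vo2,
                       ve_dry_ml_min = 3000),
            class = c("gas_series", "data.frame"))
}

# random test series: plateaus, trends and noise, mostly positive
random_vo2_series <- function(n, dt = 10) {
  base <- stats::runif(1, 300, 700)
  y <- rep(base, n)
  k <- sample(0:3, 1)
  for (i in seq_len(k)) {
    a <- sample(n, 1)
    b <- min(n, a + sample(10:max(11, n %/% 2), 1))
    y[a:b] <- y[a:b] + stats::runif(1, -0.4, 0.4) * base
  }
  y <- y + seq(0, stats::runif(1, -0.2, 0.2) * base, length.out = n)
  y <- y + stats::rnorm(n, 0, stats::runif(1, 0.005, 0.06) * base)
  as_gas_series(y, dt)
}

# record-level cohort simulator for the statistics tests: a quadratic thermal
# response on coded Ta with individual random intercepts and Gaussian noise
simulate_records <- function(n_pop = 2, n_ind = 6, ta = seq(6, 34, 4),
                             beta = c(2.0, -0.5, 0.25), sd_ind = 0.3,
                             sd_res = 0.2, pop_shift = 0,
                             variable = "vo2_mi") {
  z <- (ta - mean(ta)) / stats::sd(ta)
  rows <- list()
  for (p in seq_len(n_pop)) {
    for (i in seq_len(n_ind)) {
      u <- stats::rnorm(1, 0, sd_ind)
      y <- beta[1] + (p - 1) * pop_shift + beta[2] * z + beta[3] * z^2 + u +
        stats::rnorm(length(ta), 0, sd_res)
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = sprintf("p%d_i%02d", p, i),
        population_id = paste0("pop", p),
        ta_C = ta, y = y, stringsAsFactors = FALSE)
    }
  }
  d <- do.call(rbind, rows)
  names(d)[names(d) == "y"] <- variable
  d
}

# linear RWE truth for PRWE recovery: rwe(ta) = 1 + slope*(prwe - ta)
simulate_rwe_records <- function(prwe_true = 10.4, slope = 0.05, n_ind = 6,
                                 ta = seq(6, 34, 4), sd_ind = 0.03,
                                 sd_res = 0.05) {
  rows <- list()
  for (i in seq_len(n_ind)) {
    u <- stats::rnorm(1, 0, sd_ind)
    rwe <- 1 + slope * (prwe_true - ta) + u + stats::rnorm(length(ta), 0, sd_res)
    rows[[i]] <- data.frame(animal_id = sprintf("i%02d", i),
                            population_id = "pop1", ta_C = ta, rwe = rwe,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# forward dry-gas mixing used to check the mass-balance inversion: given a
# (vo2, vco2) truth, compute excurrent fractions from first principles
forward_mix <- function(vo2_ml_h, vco2_ml_h, ewl_mg_h, flow_ml_min,
                        fi_o2 = 0.2095, fi_co2 = 0.0004, bp_kPa = 101.325,
                        t_C = 25) {
  vo2 <- vo2_ml_h / 60
  vco2 <- vco2_ml_h / 60
  ve <- flow_ml_min - vo2 + vco2
  vw <- ewl_mg_h / 60 / 18.016 * 22.414
  pw <- bp_kPa * vw / (ve + vw)
  list(fe_o2 = (flow_ml_min * fi_o2 - vo2) / ve,
       fe_co2 = (flow_ml_min * fi_co2 + vco2) / ve,
       rh_pct = 100 * pw / (0.61094 * exp(17.625 * t_C / (t_C + 243.04))),
       ve_dry = ve)
}

# tiny chamber config for fast end-to-end tests (same physics, short trial)
fast_chamber <- function(...) {
  args <- utils::modifyList(list(animal_s = 5400, baseline_s = 1200,
                                 sample_interval_s = 15), list(...))
  do.call(chamber_config, args)
}
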