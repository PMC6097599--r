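#' Fit a quadratic thermal-response mixed model
#'
#' Fits `variable ~ Ta + Ta^2 + (1 | animal_id)` by REML (lme4), with ambient
#' temperature centered and scaled to unit SD before polynomial expansion so
#' the linear and quadratic coefficients are on comparable scales. The coding
#' (center, scale) is stored with the fit and all predictions are made on the
#' raw Ta scale, so results do not depend on the coding.
#'
#' @param records a physiological record table (one row per trial) with
#'   columns `animal_id`, `ta_C`, `population_id` and the response variable.
#' @param variable name of the response column (e.g. `"vo2_mi"`, `"rwe"`).
#' @param population optional population id to subset to; required when
#'   `records` holds several populations.
#' @param coding optional `c(center, scale)` to reuse an existing Ta coding.
#' @return object of class `thermal_fit`: coefficients (intercept, linear,
#'   quadratic on the coded scale) with standard errors, random-intercept and
#'   residual variances, the coding descriptor, `boundary` flag for singular
#'   fits, and the underlying `lmerMod`.
#' @export
fit_thermal_response <- function(records, variable, population = NULL,
                                 coding = NULL) {
  d <- prepare_records(records, variable, population)
  if (length(unique(d$animal_id)) < 2) {
    stop("need at least 2 individuals to separate random and residual variance")
  }
  if (length(unique(d$ta_C)) < 3) {
    stop("need at least 3 distinct Ta values for a quadratic fit")
  }
  if (is.null(coding)) {
    coding <- c(center = mean(d$ta_C), scale = stats::sd(d$ta_C))
  }
  d$z <- (d$ta_C - coding[["center"]]) / coding[["scale"]]
  d$z2 <- d$z^2
  fit <- lme4::lmer(y ~ z + z2 + (1 | animal_id), data = d, REML = TRUE)
  sm <- summary(fit)
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    population_id = population %||% unique(d$population_id)[1],
    variable = variable,
    coefficients = stats::setNames(lme4::fixef(fit),
                                   c("intercept", "ta", "ta2")),
    se = stats::setNames(sm$coefficients[, "Std. Error"],
                         c("intercept", "ta", "ta2")),
    var_individual = vc$vcov[vc$grp == "animal_id"],
    var_residual = vc$vcov[vc$grp == "Residual"],
    n_individuals = length(unique(d$animal_id)),
    n_obs = nrow(d),
    coding = coding,
    ta_range = range(d$ta_C),
    boundary = lme4::isSingular(fit),
    model = fit,
    data = d
  ), class = "thermal_fit")
}

prepare_records <- function(records, variable, population = NULL) {
  stopifnot(is.data.frame(records))
  for (col in c("animal_id", "ta_C", variable)) {
    if (!col %in% names(records)) stop("records lack column ", col)
  }
  if (!"population_id" %in% names(records)) records$population_id <- "pop"
  if (!is.null(population)) {
    records <- records[records$population_id == population, ]
    if (nrow(records) == 0) stop("no records for population ", population)
  } else if (length(unique(records$population_id)) > 1) {
    stop("records hold several populations; pass `population`")
  }
  d <- data.frame(y = records[[variable]], ta_C = records$ta_C,
                  animal_id = factor(records$animal_id),
                  population_id = records$population_id)
  d <- d[is.finite(d$y) & is.finite(d$ta_C), ]
  if (nrow(d) == 0) stop("no finite observations for ", variable)
  d
}

#' @export
print.thermal_fit <- function(x, ...) {
  cat(sprintf("<thermal_fit> %s ~ quadratic(Ta), population %s\n",
              x$variable, x$population_id))
  cat(sprintf("  coding: z = (Ta - %.3f)/%.3f\n",
              x$coding[["center"]], x$coding[["scale"]]))
  co <- sprintf("%.4g +/- %.3g", x$coefficients, x$se)
  cat("  intercept ", co[1], ", z ", co[2], ", z^2 ", co[3], "\n", sep = "")
  cat(sprintf("  var(individual) %.4g, var(residual) %.4g%s; N=%d, n=%d\n",
              x$var_individual, x$var_residual,
              if (x$boundary) " [boundary]" else "",
              x$n_individuals, x$n_obs))
  invisible(x)
}

#' Predict the fitted thermal response at raw ambient temperatures
#'
#' @param object a [fit_thermal_response()] result.
#' @param ta_C ambient temperatures (degC, raw scale).
#' @param ... unused.
#' @return fixed-effect predictions (population-level curve).
#' @export
predict.thermal_fit <- function(object, ta_C, ...) {
  z <- (ta_C - object$coding[["center"]]) / object$coding[["scale"]]
  b <- object$coefficients
  unname(b[1] + b[2] * z + b[3] * z^2)
}

#' Likelihood ratio test of the individual random effect
#'
#' Refits the thermal-response model by maximum likelihood with and without
#' the random intercept (same fixed structure, same data) and forms
#' 2*(logLik_full - logLik_null). Because the variance is tested on its
#' boundary, the reference distribution is the 50:50 mixture of chi-squared
#' with 0 and 1 degrees of freedom: p = 0.5 P(chi2_1 >= stat) for stat > 0
#' and 1 at stat = 0.
#'
#' @param fit a [fit_thermal_response()] result.
#' @return list with `statistic`, `p`, and the two log-likelihoods.
#' @export
lrt_random_effect <- function(fit) {
  stopifnot(inherits(fit, "thermal_fit"))
  d <- fit$data
  m1 <- lme4::lmer(y ~ z + z2 + (1 | animal_id), data = d, REML = FALSE)
  m0 <- stats::lm(y ~ z + z2, data = d)
  ll1 <- as.numeric(stats::logLik(m1))
  ll0 <- as.numeric(stats::logLik(m0))
  stat <- max(0, 2 * (ll1 - ll0))
  p <- if (stat < 1e-8) 1 else 0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE)
  list(statistic = stat, p = p, logLik_full = ll1, logLik_null = ll0)
}

#' Compare populations' thermal responses in one joint mixed model
#'
#' Fits `variable ~ (Ta + Ta^2) * population + (1 | animal_id)` (Ta centered
#' and scaled across all populations, REML) with the declared reference
#' population as the baseline level. Reports large-sample Wald chi-squared
#' tests for the population main effect and the Ta-by-population interaction,
#' per-population contrasts against the reference (Wald z at the Ta center),
#' and the boundary-corrected likelihood ratio test of the random effect.
#'
#' @param records record table with at least two populations.
#' @param variable response column name.
#' @param reference reference population id (e.g. the most arid-habitat one).
#' @return object of class `location_comparison`.
#' @export
compare_locations <- function(records, variable, reference) {
  stopifnot(is.data.frame(records))
  pops <- unique(records$population_id)
  if (length(pops) < 2) stop("need at least 2 populations to compare")
  if (!reference %in% pops) stop("reference population not present: ", reference)
  d <- data.frame(y = records[[variable]], ta_C = records$ta_C,
                  animal_id = factor(paste(records$population_id,
                                           records$animal_id, sep = ":")),
                  pop = stats::relevel(factor(records$population_id),
                                       ref = reference))
  d <- d[is.finite(d$y) & is.finite(d$ta_C), ]
  coding <- c(center = mean(d$ta_C), scale = stats::sd(d$ta_C))
  d$z <- (d$ta_C - coding[["center"]]) / coding[["scale"]]
  d$z2 <- d$z^2
  full <- lme4::lmer(y ~ (z + z2) * pop + (1 | animal_id), data = d, REML = TRUE)
  beta <- lme4::fixef(full)
  V <- as.matrix(stats::vcov(full))
  nm <- names(beta)
  main_idx <- grep("^pop", nm)
  int_idx <- grep("^z2?:pop", nm)
  wald <- rbind(wald_chisq(beta, V, main_idx, "population"),
                wald_chisq(beta, V, int_idx, "ta_x_population"))
  est <- beta[main_idx]
  se <- sqrt(diag(V)[main_idx])
  zstat <- est / se
  contrasts <- data.frame(
    population = sub("^pop", "", nm[main_idx]),
    reference = reference,
    estimate = unname(est), se = unname(se), z = unname(zstat),
    p = 2 * stats::pnorm(-abs(zstat)),
    stringsAsFactors = FALSE)
  m1 <- lme4::lmer(y ~ (z + z2) * pop + (1 | animal_id), data = d, REML = FALSE)
  m0 <- stats::lm(y ~ (z + z2) * pop, data = d)
  lstat <- max(0, 2 * (as.numeric(stats::logLik(m1)) - as.numeric(stats::logLik(m0))))
  lrt <- list(statistic = lstat,
              p = if (lstat < 1e-8) 1
                  else 0.5 * stats::pchisq(lstat, 1, lower.tail = FALSE))
  structure(list(variable = variable, reference = reference,
                 coding = coding, wald = wald, contrasts = contrasts,
                 lrt_random = lrt, boundary = lme4::isSingular(full),
                 n_obs = nrow(d),
                 n_individuals = length(unique(d$animal_id)),
                 model = full),
            class = "location_comparison")
}

wald_chisq <- function(beta, V, idx, effect) {
  b <- beta[idx]
  W <- as.numeric(t(b) %*% solve(V[idx, idx, drop = FALSE]) %*% b)
  data.frame(effect = effect, chisq = W, df = length(idx),
             p = stats::pchisq(W, df = length(idx), lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' @export
print.location_comparison <- function(x, ...) {
  cat(sprintf("<location_comparison> %s, reference %s (N=%d, n=%d)\n",
              x$variable, x$reference, x$n_individuals, x$n_obs))
  print(x$wald, row.names = FALSE)
  cat(sprintf("  LRT random effect: stat %.3f, p %.4g\n",
              x$lrt_random$statistic, x$lrt_random$p))
  invisible(x)
}

#' Fitted relative-water-economy curve as a plain quadratic
#'
#' Builds the object [estimate_prwe()] roots: `value(ta) = intercept +
#' linear*z + quad*z^2` with `z = (ta - center)/scale`. Useful for supplying
#' a known curve directly.
#'
#' @param intercept,linear,quad coefficients on the coded scale.
#' @param center,scale Ta coding (defaults: raw scale).
#' @param ta_range measured Ta range `c(min, max)` used to select roots and
#'   flag extrapolation.
#' @return object of class `thermal_curve`.
#' @export
thermal_curve <- function(intercept, linear, quad = 0, center = 0, scale = 1,
                          ta_range = c(5, 35)) {
  structure(list(coefficients = c(intercept = intercept, ta = linear, ta2 = quad),
                 coding = c(center = center, scale = scale),
                 ta_range = ta_range),
            class = "thermal_curve")
}

#' Estimate the point of relative water economy (PRWE)
#'
#' PRWE is the ambient temperature at which relative water economy
#' (MWP/EWL) equals 1. The RWE thermal response is fitted as a quadratic
#' mixed model (or supplied as a fitted curve) and the root of
#' `RWE(Ta) = 1` is found by bisection on the fitted curve; with a quadratic,
#' the real root nearest the measured Ta range is returned. Roots outside
#' the measured range plus `pad` degrees are reported with
#' `extrapolated = TRUE`.
#'
#' @param x a record table (a `data.frame`), a `thermal_fit` of variable
#'   `"rwe"`, or a [thermal_curve()].
#' @param population population id (needed for multi-population record tables).
#' @param pad extrapolation margin (degC, default 5).
#' @return list with `prwe_C` (NA when undefined), `extrapolated`, and
#'   `status` (`"ok"`, `"degenerate"` when the curve is identically 1, or
#'   `"no_root"`).
#' @export
estimate_prwe <- function(x, population = NULL, pad = 5) {
  if (is.data.frame(x)) {
    x <- fit_thermal_response(x, "rwe", population)
  }
  if (!inherits(x, c("thermal_fit", "thermal_curve"))) {
    stop("x must be a record table, thermal_fit or thermal_curve")
  }
  if (inherits(x, "thermal_fit") && !identical(x$variable, "rwe")) {
    stop("PRWE needs a fit of variable 'rwe', got ", x$variable)
  }
  b <- x$coefficients
  cen <- x$coding[["center"]]
  sc <- x$coding[["scale"]]
  # raw-scale quadratic A ta^2 + B ta + C
  A <- b[[3]] / sc^2
  B <- b[[2]] / sc - 2 * b[[3]] * cen / sc^2
  C <- b[[1]] - b[[2]] * cen / sc + b[[3]] * cen^2 / sc^2
  rng <- x$ta_range
  scale_ref <- max(abs(c(A * mean(rng)^2, B * mean(rng), C, 1)))
  if (abs(A) < 1e-12 * scale_ref && abs(B) < 1e-12 * scale_ref) {
    if (abs(C - 1) < 1e-8 * scale_ref) {
      return(list(prwe_C = NA_real_, extrapolated = NA,
                  status = "degenerate", population = x$population_id %||% NA))
    }
    return(list(prwe_C = NA_real_, extrapolated = NA, status = "no_root",
                population = x$population_id %||% NA))
  }
  roots <- quadratic_roots(A, B, C - 1)
  if (length(roots) == 0) {
    return(list(prwe_C = NA_real_, extrapolated = NA, status = "no_root",
                population = x$population_id %||% NA))
  }
  # refine each root by bisection on the fitted curve around the candidate
  f <- function(ta) {
    z <- (ta - cen) / sc
    b[[1]] + b[[2]] * z + b[[3]] * z^2 - 1
  }
  roots <- vapply(roots, function(r) refine_root(f, r), numeric(1))
  dist <- pmax(pmax(rng[1] - roots, roots - rng[2]), 0)
  root <- roots[order(dist, roots)][1]
  list(prwe_C = unname(root),
       extrapolated = root < rng[1] - pad || root > rng[2] + pad,
       status = "ok",
       population = x$population_id %||% NA)
}

quadratic_roots <- function(A, B, C) {
  if (abs(A) < 1e-14 * max(abs(B), 1)) {
    return(-C / B)
  }
  disc <- B^2 - 4 * A * C
  if (disc < 0) return(numeric(0))
  # numerically stable form
  q <- -(B + sign(B + (B == 0)) * sqrt(disc)) / 2
  unique(c(q / A, if (q != 0) C / q else -B / A))
}

# bisection refinement within +/- 0.5 degC of an analytic candidate;
# tolerance is floored at a few ULP so large-magnitude roots terminate
refine_root <- function(f, r, half_width = 0.5, tol = 1e-10) {
  lo <- r - half_width
  hi <- r + half_width
  flo <- f(lo)
  fhi <- f(hi)
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) return(r)
  tol <- max(tol, 4 * .Machine$double.eps * max(abs(lo), abs(hi)))
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
    if (hi - lo <= tol) break
  }
  (lo + hi) / 2
}

#' One-way ANOVA with Student-Newman-Keuls letter groupings
#'
#' Compares a standard value among populations with a one-way ANOVA, then
#' groups ordered means with the stepwise Student-Newman-Keuls procedure on
#' the studentized range: the full range of k means is tested at
#' `qtukey(1 - alpha, k, df)`; a significant stretch is split into its two
#' sub-stretches of size k-1 and so on; stretches inside an accepted
#' (non-significant) stretch are not tested. Unequal group sizes use the
#' harmonic mean n. Groups sharing a letter are not significantly different
#' at `alpha`.
#'
#' @param records record table (typically trials at thermoneutral Ta).
#' @param variable response column name.
#' @param group grouping column (default `"population_id"`).
#' @param alpha significance level (default 0.05).
#' @return object of class `snk_result`: ANOVA F, df, p, and a `groups`
#'   data.frame (group, n, mean, se, letters) ordered by mean.
#' @export
anova_snk <- function(records, variable, group = "population_id",
                      alpha = 0.05) {
  stopifnot(is.data.frame(records))
  y <- records[[variable]]
  g <- factor(records[[group]])
  keep <- is.finite(y) & !is.na(g)
  y <- y[keep]; g <- droplevels(g[keep])
  if (nlevels(g) < 2) stop("need at least 2 groups")
  n <- tapply(y, g, length)
  if (any(n < 2)) stop("every group needs at least 2 observations")
  fit <- stats::aov(y ~ g)
  an <- suppressWarnings(stats::anova(fit))
  mse <- an["Residuals", "Mean Sq"]
  df_err <- an["Residuals", "Df"]
  if (!is.finite(mse) || mse <= 1e-10 * stats::var(y)) {
    stop("zero within-group variance: SNK undefined")
  }
  means <- tapply(y, g, mean)
  letters_by_group <- snk_grouping(means, n, mse, df_err, alpha)
  ord <- order(means)
  groups <- data.frame(
    group = names(means)[ord],
    n = as.integer(n[ord]),
    mean = unname(means[ord]),
    se = unname(sqrt(mse / n[ord])),
    letters = unname(letters_by_group[ord]),
    stringsAsFactors = FALSE)
  structure(list(variable = variable, alpha = alpha,
                 F = an["g", "F value"], df = c(an["g", "Df"], df_err),
                 p = an["g", "Pr(>F)"], mse = mse, groups = groups),
            class = "snk_result")
}

#' Student-Newman-Keuls letter grouping of means
#'
#' Stepwise studentized-range procedure on ordered means; exported so the
#' grouping can be driven directly from summary statistics.
#'
#' @param means named vector of group means.
#' @param n group sizes (scalar or named vector; harmonic mean is used).
#' @param mse within-group mean square from the ANOVA.
#' @param df error degrees of freedom.
#' @param alpha significance level.
#' @return named character vector of letter strings, one per group.
#' @export
snk_grouping <- function(means, n, mse, df, alpha = 0.05) {
  k <- length(means)
  stopifnot(k >= 2)
  if (length(n) == 1) n <- rep(n, k)
  n_h <- k / sum(1 / n)
  se <- sqrt(mse / n_h)
  ord <- order(means)
  m <- means[ord]
  accepted <- list()
  tested <- new.env(parent = emptyenv())
  test_stretch <- function(i, j) {
    if (j <= i) return(invisible())
    key <- paste(i, j)
    if (!is.null(tested[[key]])) return(invisible())
    tested[[key]] <- TRUE
    q_obs <- (m[j] - m[i]) / se
    q_crit <- stats::qtukey(1 - alpha, nmeans = j - i + 1, df = df)
    if (q_obs <= q_crit) {
      accepted[[length(accepted) + 1L]] <<- c(i, j)
    } else {
      test_stretch(i, j - 1)
      test_stretch(i + 1, j)
    }
  }
  test_stretch(1, k)
  # maximal homogeneous stretches (drop stretches nested in a wider one)
  stretches <- c(accepted, lapply(seq_len(k), function(i) c(i, i)))
  keep <- vapply(seq_along(stretches), function(a) {
    sa <- stretches[[a]]
    !any(vapply(seq_along(stretches), function(b) {
      sb <- stretches[[b]]
      a != b && sb[1] <= sa[1] && sb[2] >= sa[2] &&
        (sb[2] - sb[1]) > (sa[2] - sa[1])
    }, logical(1)))
  }, logical(1))
  stretches <- unique(stretches[keep])
  starts <- vapply(stretches, `[`, numeric(1), 1)
  stretches <- stretches[order(starts)]
  lab <- rep("", k)
  for (s in seq_along(stretches)) {
    rng <- stretches[[s]]
    lab[rng[1]:rng[2]] <- paste0(lab[rng[1]:rng[2]], letters[s])
  }
  out <- stats::setNames(rep("", k), names(means))
  out[ord] <- lab
  out
}

#' @export
print.snk_result <- function(x, ...) {
  cat(sprintf("<snk_result> %s: F(%d, %d) = %.3f, p = %.4g (alpha %.2f)\n",
              x$variable, x$df[1], x$df[2], x$F, x$p, x$alpha))
  print(x$groups, row.names = FALSE)
  invisible(x)
}
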