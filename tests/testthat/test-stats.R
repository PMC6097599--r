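test_that("noise-free quadratic data are recovered to 1e-6", {
  ta <- seq(6, 34, 4)
  truth <- 2 - 0.1 * ta + 0.005 * ta^2
  recs <- do.call(rbind, lapply(1:4, function(i) {
    data.frame(animal_id = paste0("i", i), population_id = "p", ta_C = ta,
               vo2_mi = truth)
  }))
  # a zero-residual interpolation limit: lmer warns about the perfect fit
  fit <- suppressWarnings(suppressMessages(fit_thermal_response(recs, "vo2_mi")))
  expect_equal(predict(fit, ta), truth, tolerance = 1e-6)
  raw <- suppressWarnings(suppressMessages(
    fit_thermal_response(recs, "vo2_mi", coding = c(center = 0, scale = 1))))
  expect_equal(unname(raw$coefficients), c(2, -0.1, 0.005), tolerance = 1e-6)
})

test_that("a fit with no between-individual variance is flagged at the boundary", {
  ta <- seq(6, 34, 4)
  set.seed(12)
  noise <- rnorm(length(ta), 0, 0.2)  # same residuals for every individual:
  recs <- do.call(rbind, lapply(1:4, function(i) {  # between-variance exactly 0
    data.frame(animal_id = paste0("i", i), population_id = "p", ta_C = ta,
               vo2_mi = 2 - 0.1 * ta + 0.005 * ta^2 + noise)
  }))
  fit <- suppressMessages(fit_thermal_response(recs, "vo2_mi"))
  expect_true(fit$boundary)
  expect_equal(fit$var_individual, 0, tolerance = 1e-10)
})

test_that("predictions are invariant to the Ta coding", {
  set.seed(31)
  recs <- simulate_records(n_pop = 1, n_ind = 6)
  f1 <- fit_thermal_response(recs, "vo2_mi")
  f2 <- fit_thermal_response(recs, "vo2_mi", coding = c(center = 0, scale = 1))
  ta <- seq(6, 34, 0.5)
  expect_equal(predict(f1, ta), predict(f2, ta), tolerance = 1e-8)
  # refitting the same data reproduces coefficients
  f3 <- fit_thermal_response(recs, "vo2_mi")
  expect_equal(f1$coefficients, f3$coefficients, tolerance = 1e-8)
})

test_that("guards: one individual, too few Ta levels, multiple populations", {
  set.seed(5)
  recs <- simulate_records(n_pop = 1, n_ind = 1)
  expect_error(fit_thermal_response(recs, "vo2_mi"), "2 individuals")
  recs2 <- simulate_records(n_pop = 1, n_ind = 6, ta = c(10, 20))
  expect_error(fit_thermal_response(recs2, "vo2_mi"), "3 distinct")
  recs3 <- simulate_records(n_pop = 2, n_ind = 4)
  expect_error(fit_thermal_response(recs3, "vo2_mi"), "population")
})

test_that("random-effect LRT: null limit and recoding invariance", {
  set.seed(77)
  recs <- simulate_records(n_pop = 1, n_ind = 8, sd_ind = 0, sd_res = 0.2)
  fit <- fit_thermal_response(recs, "vo2_mi")
  lrt <- lrt_random_effect(fit)
  expect_lt(lrt$statistic, 1)     # no between-individual variance
  expect_gt(lrt$p, 0.15)
  # statistic invariant to Ta recoding
  fit_raw <- fit_thermal_response(recs, "vo2_mi",
                                  coding = c(center = 0, scale = 1))
  expect_equal(lrt$statistic, lrt_random_effect(fit_raw)$statistic,
               tolerance = 1e-6)
})

test_that("random-effect LRT has power under strong clustering", {
  set.seed(88)
  hits <- 0
  for (i in 1:30) {
    recs <- simulate_records(n_pop = 1, n_ind = 8, sd_ind = 0.6, sd_res = 0.2)
    lrt <- lrt_random_effect(fit_thermal_response(recs, "vo2_mi"))
    hits <- hits + (lrt$p < 0.05)
  }
  expect_gte(hits, 29)  # 3:1 SD ratio: near-certain detection
})

test_that("location comparison detects a built-in shift and guards inputs", {
  set.seed(91)
  recs <- simulate_records(n_pop = 2, n_ind = 6, sd_ind = 0.1, sd_res = 0.2,
                           pop_shift = 1.0)  # 5 residual SDs
  lc <- compare_locations(recs, "vo2_mi", reference = "pop1")
  expect_lt(lc$wald$p[lc$wald$effect == "population"], 0.001)
  expect_equal(lc$contrasts$estimate, 1.0, tolerance = 0.35)
  expect_error(compare_locations(recs, "vo2_mi", reference = "nope"), "reference")
  one <- recs[recs$population_id == "pop1", ]
  expect_error(compare_locations(one, "vo2_mi", reference = "pop1"), "2 populations")
})

test_that("permuting population labels destroys a true effect", {
  set.seed(17)
  recs <- simulate_records(n_pop = 2, n_ind = 6, sd_ind = 0.1, sd_res = 0.2,
                           pop_shift = 1.0)
  lc <- compare_locations(recs, "vo2_mi", reference = "pop1")
  # permute population labels at the individual level
  ids <- unique(recs$animal_id)
  new_pop <- setNames(sample(rep(c("pop1", "pop2"), length.out = length(ids))),
                      ids)
  recs$population_id <- new_pop[recs$animal_id]
  lcp <- compare_locations(recs, "vo2_mi", reference = "pop1")
  expect_lt(lc$wald$p[1], 1e-4)
  expect_gt(lcp$wald$p[1], 0.01)
})

test_that("PRWE: linear root, degenerate curve, no real root", {
  est <- estimate_prwe(thermal_curve(2.5, -0.10, ta_range = c(6, 34)))
  expect_equal(est$prwe_C, 15.0, tolerance = 1e-9)
  expect_false(est$extrapolated)
  expect_identical(est$status, "ok")

  deg <- estimate_prwe(thermal_curve(1, 0, 0, ta_range = c(6, 34)))
  expect_identical(deg$status, "degenerate")
  expect_true(is.na(deg$prwe_C))

  none <- estimate_prwe(thermal_curve(2, 0, 0.5, center = 20, scale = 10,
                                      ta_range = c(6, 34)))
  expect_identical(none$status, "no_root")

  # quadratic with two roots: the one nearest the measured range is returned
  # curve: 1 + (ta-15)(ta-60)/200 -> roots at 15 and 60
  two <- estimate_prwe(thermal_curve(1 + 15 * 60 / 200, -(75) / 200, 1 / 200,
                                     ta_range = c(6, 34)))
  expect_equal(two$prwe_C, 15, tolerance = 1e-6)

  far <- estimate_prwe(thermal_curve(3, -0.05, ta_range = c(6, 34)))
  expect_equal(far$prwe_C, 40, tolerance = 1e-6)
  expect_true(far$extrapolated)
})

test_that("PRWE is recovered from noisy cohorts", {
  set.seed(1234)
  ests <- replicate(25, {
    recs <- simulate_rwe_records(prwe_true = 10.4)
    estimate_prwe(recs)$prwe_C
  })
  expect_true(all(abs(ests - 10.4) < 1.5))
  expect_lt(abs(mean(ests) - 10.4), 0.3)
})

test_that("SNK letters match the studentized-range construction", {
  set.seed(3)
  g <- rep(c("a", "b", "c"), each = 6)
  y <- rep(c(1, 1, 5), each = 6) + rnorm(18, 0, 0.1)
  res <- anova_snk(data.frame(population_id = g, v = y), "v")
  expect_lt(res$p, 1e-10)
  lets <- setNames(res$groups$letters, res$groups$group)
  expect_identical(unname(lets["a"]), unname(lets["b"]))
  expect_false(lets["c"] %in% lets[c("a", "b")])
  expect_identical(length(unique(res$groups$letters)), 2L)
})

test_that("SNK grouping equals an exhaustive stepwise oracle (<= 5 groups)", {
  # independent oracle: same procedure written as a queue over stretches
  snk_oracle <- function(means, n_h, mse, df, alpha) {
    k <- length(means)
    ord <- order(means)
    m <- means[ord]
    se <- sqrt(mse / n_h)
    accepted <- list()
    queue <- list(c(1, k))
    seen <- character()
    while (length(queue) > 0) {
      ij <- queue[[1]]; queue <- queue[-1]
      key <- paste(ij, collapse = "-")
      if (key %in% seen || ij[2] <= ij[1]) next
      seen <- c(seen, key)
      q <- (m[ij[2]] - m[ij[1]]) / se
      if (q <= qtukey(1 - alpha, ij[2] - ij[1] + 1, df)) {
        accepted[[length(accepted) + 1]] <- ij
      } else {
        queue <- c(queue, list(c(ij[1], ij[2] - 1)), list(c(ij[1] + 1, ij[2])))
      }
    }
    # which ordered pairs are declared homogeneous
    homog <- matrix(FALSE, k, k)
    diag(homog) <- TRUE
    for (ij in accepted) {
      homog[ij[1]:ij[2], ij[1]:ij[2]] <- TRUE
    }
    homog
  }
  set.seed(64)
  for (rep in 1:40) {
    k <- sample(2:5, 1)
    means <- setNames(rnorm(k, 10, 2), paste0("g", 1:k))
    n_h <- sample(3:8, 1)
    mse <- runif(1, 0.05, 4)
    df <- sample(10:40, 1)
    lets <- snk_grouping(means, n_h, mse, df, alpha = 0.05)
    homog <- snk_oracle(means, n_h, mse, df, alpha = 0.05)
    ord <- order(means)
    for (i in 1:(k - 1)) {
      for (j in (i + 1):k) {
        share <- any(strsplit(lets[ord[i]], "")[[1]] %in%
                       strsplit(lets[ord[j]], "")[[1]])
        expect_identical(share, homog[i, j],
                         info = sprintf("rep %d pair %d-%d", rep, i, j))
      }
    }
  }
})

test_that("SNK guards degenerate inputs", {
  d <- data.frame(population_id = rep("a", 6), v = rnorm(6))
  expect_error(anova_snk(d, "v"), "2 groups")
  d2 <- data.frame(population_id = rep(c("a", "b"), each = 3),
                   v = rep(c(1, 2), each = 3))
  expect_error(suppressWarnings(anova_snk(d2, "v")), "variance")
})
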