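# Repeatability study: trial machinery, closed-form OLS, report conventions.

test_that("zero operator noise gives identical trials and perfect repeatability", {
  stacked <- zero_noise_trials()
  g1 <- dplyr::filter(stacked, trial == 1)$mean_strain
  g2 <- dplyr::filter(stacked, trial == 2)$mean_strain
  g3 <- dplyr::filter(stacked, trial == 3)$mean_strain
  expect_identical(g1, g2)
  expect_identical(g1, g3)
  rep <- repeatability_report(stacked)
  expect_equal(rep$n_cells, 48)
  expect_identical(rep$results$slope, rep(0, 48))
  expect_true(all(rep$results$zero_variance))
  expect_identical(rep$fraction_repeatable, 1)
})

test_that("seeded trials are reproducible and noisy trials differ", {
  lm <- canonical_lm()
  noise <- operator_noise(0.25, seed = 5)
  # cheap configuration: two trials, two scenarios
  sc <- default_scenarios()[1:2, ]
  s1 <- run_trials(lm, noise, n_trials = 2, scenarios = sc)
  s2 <- run_trials(lm, noise, n_trials = 2, scenarios = sc)
  expect_identical(s1$mean_strain, s2$mean_strain)
  t1 <- dplyr::filter(s1, trial == 1)$mean_strain
  t2 <- dplyr::filter(s1, trial == 2)$mean_strain
  expect_true(all(t1 != t2))
  expect_error(run_trials(lm, noise, n_trials = 1),
               class = "sijstrain_invalid_parameter")
})

test_that("OLS slope matches the closed-form reference to 1e-12", {
  y <- c(0.010, 0.012, 0.011, 0.013, 0.012)
  res <- ols_slope(y)
  ref <- lm(y ~ x, data = data.frame(y = y, x = 1:5))
  ci <- confint(ref, "x", level = 0.95)
  sm <- summary(ref)$coefficients
  expect_equal(res$slope, unname(sm["x", "Estimate"]), tolerance = 1e-12)
  expect_equal(res$intercept, unname(sm["(Intercept)", "Estimate"]), tolerance = 1e-12)
  expect_equal(res$se, unname(sm["x", "Std. Error"]), tolerance = 1e-12)
  expect_equal(res$p_value, unname(sm["x", "Pr(>|t|)"]), tolerance = 1e-12)
  expect_equal(res$ci_lower, unname(ci[1]), tolerance = 1e-12)
  expect_equal(res$ci_upper, unname(ci[2]), tolerance = 1e-12)

  set.seed(11)
  for (i in 1:25) {
    n <- sample(4:9, 1)
    yy <- rnorm(n)
    r <- ols_slope(yy)
    rf <- summary(lm(yy ~ t, data = data.frame(yy = yy, t = seq_len(n))))$coefficients
    expect_equal(r$slope, unname(rf["t", "Estimate"]), tolerance = 1e-10)
    expect_equal(r$p_value, unname(rf["t", "Pr(>|t|)"]), tolerance = 1e-10)
  }
})

test_that("degenerate series follow the stated conventions", {
  const <- ols_slope(rep(0.07, 5))
  expect_identical(const$slope, 0)
  expect_true(const$zero_variance)
  expect_true(is.na(const$p_value))
  exact <- ols_slope(c(1, 2, 3, 4, 5))
  expect_equal(exact$slope, 1)
  expect_true(exact$perfect_fit)
  expect_identical(exact$p_value, 0)
  expect_error(ols_slope(numeric(1)), class = "sijstrain_insufficient_data")
})

test_that("the slope test is calibrated under the i.i.d. null and powered against drift", {
  set.seed(99)
  rate <- mean(replicate(2000, ols_slope(rnorm(5))$p_value < 0.05))
  expect_lt(abs(rate - 0.05), 0.02)
  set.seed(7)
  power <- mean(replicate(200, {
    ols_slope(0.002 * (1:5) + rnorm(5, sd = 2e-4))$p_value < 0.05
  }))
  expect_gt(power, 0.9)
})

test_that("the repeatability report is complete, classed and tidied", {
  rep <- repeatability_report(zero_noise_trials())
  expect_s3_class(rep, "sij_repeatability")
  td <- tidy(rep)
  expect_equal(nrow(td), 48)
  expect_true(all(c("scenario", "group", "side", "slope", "ci_lower",
                    "ci_upper", "p_value", "repeatable") %in% names(td)))
  gl <- glance(rep)
  expect_identical(gl$n_repeatable, 48L)
  # incomplete grids are refused with a count of missing cells
  broken <- dplyr::filter(zero_noise_trials(), !(trial == 2 & scenario == 1))
  expect_error(repeatability_report(broken), class = "sijstrain_aggregation_error")
})

test_that("cells with injected linear drift are detected as non-repeatable", {
  stacked <- zero_noise_trials()
  set.seed(21)
  drifted <- stacked %>%
    dplyr::mutate(mean_strain = mean_strain +
                    ifelse(scenario == 1 & group == "dorsal_si" & side == "L",
                           0.002 * trial, 0) +
                    rnorm(dplyr::n(), sd = 2e-5))
  rep <- repeatability_report(drifted)
  cell <- dplyr::filter(tidy(rep), scenario == 1, group == "dorsal_si", side == "L")
  expect_lt(cell$p_value, 0.05)
  expect_false(cell$repeatable)
})
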