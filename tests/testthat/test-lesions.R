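# Lesion-count cohort simulation and statistics.

test_that("cohort simulation is Poisson-faithful, seeded and covariate-consistent", {
  zero_means <- default_lesion_means() %>% dplyr::mutate(mean_total = 0)
  co0 <- simulate_cohort(means = zero_means, seed = 2)
  counts <- dplyr::select(co0, dplyr::matches("_(L|R)$"))
  expect_true(all(counts == 0))

  co1 <- simulate_cohort(seed = 5)
  co2 <- simulate_cohort(seed = 5)
  expect_identical(co1, co2)
  expect_equal(nrow(co1), 22)
  expect_true(all(co1$sex[co1$work_status == "Breeder"] == "F"))

  # law of large numbers at the Breeder subchondral-erosion default (1.58)
  big <- simulate_cohort(group_sizes = c(Breeder = 10000), seed = 8)
  tot <- big$subchondral_erosion_L + big$subchondral_erosion_R
  se <- sqrt(1.58 / 10000)
  expect_lt(abs(mean(tot) - 1.58), 3 * se)
  # Poisson: variance close to mean
  expect_lt(abs(var(tot) / mean(tot) - 1), 0.1)
  expect_error(simulate_cohort(group_sizes = c(A = 0)),
               class = "sijstrain_invalid_parameter")
})

test_that("one-way ANOVA matches stats::aov and decomposes sums of squares", {
  set.seed(31)
  for (i in 1:10) {
    g <- rep(c("a", "b", "c"), times = sample(4:9, 3, replace = TRUE))
    y <- rpois(length(g), 2) + ifelse(g == "b", rpois(length(g), 1), 0)
    res <- oneway_anova(y, g)
    ref <- summary(aov(y ~ factor(g)))[[1]]
    expect_equal(res$F, ref$`F value`[1], tolerance = 1e-10)
    expect_equal(res$p_value, ref$`Pr(>F)`[1], tolerance = 1e-10)
    expect_equal(res$ss_total, res$ss_between + res$ss_within, tolerance = 1e-10)
    expect_equal(res$ss_total, sum((y - mean(y))^2), tolerance = 1e-10)
  }
  flat <- oneway_anova(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_identical(flat$F, 0)
  expect_identical(flat$p_value, 1)
  expect_error(oneway_anova(1:3, rep("a", 3)), class = "sijstrain_invalid_parameter")
})

test_that("protected LSD obeys the protection rule and the pooled-t formula", {
  set.seed(2)
  y_null <- rnorm(30)
  g <- rep(c("a", "b", "c"), each = 10)
  an_null <- oneway_anova(y_null, g)
  stopifnot(an_null$p_value > 0.3)   # a quiet null example
  lsd_null <- protected_lsd(an_null)
  expect_false(lsd_null$protected)
  expect_true(all(!lsd_null$pairs$evaluated))
  expect_true(all(is.na(lsd_null$pairs$p_value)))

  y <- c(rnorm(10, 0, 0.2), rnorm(10, 0, 0.2), rnorm(10, 5, 0.2))
  an <- oneway_anova(y, g)
  lsd <- protected_lsd(an)
  expect_true(lsd$protected)
  pr <- lsd$pairs
  ab <- dplyr::filter(pr, group_1 == "a", group_2 == "b")
  expect_false(ab$significant)
  expect_true(all(dplyr::filter(pr, group_2 == "c")$significant))
  # pooled-variance two-sample t oracle
  for (i in seq_len(nrow(pr))) {
    d <- an$group_means
    n1 <- d$n[d$group == pr$group_1[i]]; n2 <- d$n[d$group == pr$group_2[i]]
    tref <- pr$estimate[i] / sqrt(an$mse * (1 / n1 + 1 / n2))
    pref <- 2 * pt(-abs(tref), an$df_within)
    expect_equal(pr$p_value[i], pref, tolerance = 1e-10)
  }
})

test_that("factorial ANOVA reduces to the one-way F in the balanced one-factor case", {
  set.seed(3)
  d <- data.frame(work_status = rep(c("Breeder", "Detection"), each = 8),
                  sex = "F", age_group = "younger")
  d$count <- rpois(16, 2)
  fa <- factorial_anova(d, "count")
  expect_setequal(fa$dropped, c("sex", "age_group"))
  ow <- oneway_anova(d$count, d$work_status)
  eff <- dplyr::filter(fa$effects, term == "work_status")
  expect_equal(eff$statistic, ow$F, tolerance = 1e-10)
  expect_equal(eff$p_value, ow$p_value, tolerance = 1e-10)
})

test_that("Type III factorial effects match car::Anova on a balanced design", {
  skip_if_not_installed("car")
  set.seed(17)
  d <- expand.grid(work_status = c("Breeder", "Detection", "Other"),
                   sex = c("F", "M"), age_group = c("younger", "older"),
                   rep = 1:4)
  d$count <- rpois(nrow(d), 2) + as.integer(d$sex == "M")
  fa <- factorial_anova(d, "count")
  fit <- lm(count ~ work_status + sex + age_group +
              work_status:sex + work_status:age_group,
            data = d, contrasts = list(work_status = "contr.sum",
                                       sex = "contr.sum",
                                       age_group = "contr.sum"))
  ref <- car::Anova(fit, type = 3)
  for (term in fa$effects$term) {
    expect_equal(fa$effects$statistic[fa$effects$term == term],
                 ref[term, "F value"], tolerance = 1e-8)
    expect_equal(fa$effects$sumsq[fa$effects$term == term],
                 ref[term, "Sum Sq"], tolerance = 1e-8)
  }
})

test_that("aliased design cells are reported rather than fatal", {
  set.seed(8)
  d <- data.frame(
    work_status = rep(c("Breeder", "Detection", "Other"), each = 8),
    sex = c(rep("F", 8), rep(c("F", "M"), 8)),   # Breeder has no males
    age_group = rep(c("younger", "older"), 12))
  d$count <- rpois(24, 2)
  fa <- factorial_anova(d, "count")
  expect_gt(length(fa$aliased), 0)
  expect_true(all(is.finite(fa$effects$statistic[fa$effects$df > 0])))
})

test_that("the full lesion report covers 7 types x 3 sides", {
  co <- simulate_cohort(seed = 3)
  rep <- analyze_lesions(co)
  expect_equal(nrow(rep$omnibus), 21)
  expect_setequal(unique(rep$omnibus$side), c("L", "R", "total"))
  expect_setequal(unique(rep$omnibus$lesion_type), lesion_types())
  expect_equal(nrow(rep$lsd), 21 * 3)
  # identical cohort gives identical report
  rep2 <- analyze_lesions(simulate_cohort(seed = 3))
  expect_identical(rep$omnibus, rep2$omnibus)
})

test_that("cohort CSV round trip and malformed input behave", {
  co <- simulate_cohort(seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(co, path)
  back <- read_cohort_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(co))
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,work_status", "d1,Breeder"), bad)
  expect_error(read_cohort_csv(bad), class = "sijstrain_parse_error")
})
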