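test_that("outcome probability follows the logistic-additive mechanism", {
  cfg <- generator_config(baseline_logit = 0, effects = default_effects()[0, ])
  expect_equal(outcome_probability(list(), cfg), 0.5)
  # single linear effect centred at 34.5, coefficient 0.1, value 44.5
  cfg1 <- generator_config(
    baseline_logit = 0,
    effects = data.frame(feature = "peak_ve_vco2", transform = "linear",
                         threshold = 34.5, coef = 0.1))
  expect_equal(outcome_probability(list(peak_ve_vco2 = 44.5), cfg1),
               plogis(1), tolerance = 1e-12)
  # BMI above 28 is protective: risk at 30 below risk at 25
  cfg2 <- generator_config(
    baseline_logit = 0,
    effects = data.frame(feature = "bmi", transform = "threshold_above",
                         threshold = 28, coef = -0.8))
  expect_lt(outcome_probability(list(bmi = 30), cfg2),
            outcome_probability(list(bmi = 25), cfg2))
  expect_error(outcome_probability(list(bmi = 25), cfg1), "missing required")
})

test_that("sampled cohorts have the declared schema and determinism", {
  cfg <- generator_config(n_patients = 150, seed = 5)
  tab <- sample_cohort(cfg)
  expect_equal(nrow(tab), 150)
  sch <- cohort_schema()
  expect_equal(sum(sch$group == "clinical"), 39L)
  expect_equal(sum(sch$group == "fitness"), 46L)
  expect_true(all(sch$feature %in% names(tab)))
  expect_false(anyNA(tab$death_1y))
  expect_true(all(tab$death_1y %in% c(0, 1)))
  for (i in which(sch$class == "categorical")) {
    lv <- strsplit(sch$levels[i], ",")[[1]]
    expect_true(all(tab[[sch$feature[i]]] %in% lv))
  }
  expect_identical(tab, sample_cohort(cfg))
  empty <- sample_cohort(generator_config(n_patients = 0))
  expect_equal(nrow(empty), 0)
  expect_true(all(sch$feature %in% names(empty)))
})

test_that("a null mechanism gives one-half prevalence at large n", {
  cfg <- generator_config(n_patients = 10000, seed = 8, baseline_logit = 0,
                          effects = default_effects()[0, ])
  prev <- mean(sample_cohort(cfg)$death_1y)
  expect_lt(abs(prev - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("default prevalence and marginals match the study targets", {
  cfg <- generator_config(n_patients = 1190, seed = 1)
  deaths <- sum(sample_cohort(cfg)$death_1y)
  ci <- 1.96 * sqrt(1190 * 0.055 * 0.945)
  expect_gte(deaths, 65.5 - ci)
  expect_lte(deaths, 65.5 + ci)
  big <- sample_cohort(generator_config(n_patients = 2000, seed = 2))
  expect_gte(median(big$age), 61)
  expect_lte(median(big$age), 79)
  # declared copula pair carries its rank correlation
  expect_gt(cor(big$peak_vo2, big$at_vo2, method = "spearman"), 0.6)
})

test_that("planted ventilatory-efficiency effect raises risk monotonically", {
  cfg <- generator_config(n_patients = 4000, seed = 3)
  tab <- sample_cohort(cfg)
  p <- outcome_probability(tab[, setdiff(names(tab),
                                         c("patient_id", "death_1y"))], cfg)
  q <- quantile(tab$peak_ve_vco2, c(0.25, 0.75))
  expect_gt(mean(p[tab$peak_ve_vco2 >= q[2]]),
            mean(p[tab$peak_ve_vco2 <= q[1]]))
})

test_that("missingness injection is MCAR, seeded and outcome-safe", {
  cfg <- generator_config(n_patients = 100, seed = 4)
  tab <- sample_cohort(cfg)
  expect_identical(inject_missingness(tab, 0, 1), tab)
  m1 <- inject_missingness(tab, 0.3, 42)
  m2 <- inject_missingness(tab, 0.3, 42)
  expect_identical(m1, m2)
  expect_false(anyNA(m1$death_1y))
  expect_false(anyNA(m1$patient_id))
  # heavy missingness on a 100 x 10 table: recount complete rows by hand
  small <- data.frame(patient_id = sprintf("P%03d", 1:100),
                      matrix(rnorm(1000), 100, 10), death_1y = rbinom(100, 1, 0.5))
  hi <- inject_missingness(small, 0.3, 7)
  recount <- sum(apply(hi, 1, function(r) !any(is.na(r))))
  cc <- complete_case_filter(hi)
  expect_equal(nrow(cc$table), recount)
  expect_equal(cc$excluded_count, 100 - recount)
  expect_error(inject_missingness(tab, 1, 1), "rate")
  # empirical cell rate near the nominal rate
  cells <- as.matrix(m1[, setdiff(names(m1), c("patient_id", "death_1y"))])
  expect_lt(abs(mean(is.na(cells)) - 0.3), 0.02)
})

test_that("cohort CSV round-trips and validates on read", {
  cfg <- generator_config(n_patients = 60, seed = 9, missing_rate = 0.05)
  tab <- sample_cohort(cfg)
  path <- tempfile(fileext = ".csv")
  write_cohort(tab, path)
  back <- read_cohort(path)
  expect_equal(back$death_1y, tab$death_1y)
  expect_equal(back$sex, tab$sex)
  expect_equal(back$age, tab$age, tolerance = 1e-12)
  expect_equal(is.na(back$bmi), is.na(tab$bmi))
  # unknown category label is rejected with its location
  bad <- tab
  bad$sex[3] <- "unknown_level"
  p2 <- tempfile(fileext = ".csv")
  write_cohort(bad, p2)
  expect_error(read_cohort(p2), "unknown_level")
  # missing outcome is rejected
  bad2 <- tab
  bad2$death_1y[2] <- NA
  p3 <- tempfile(fileext = ".csv")
  suppressWarnings(write_cohort(bad2, p3))
  expect_error(read_cohort(p3), "missing outcome")
})

test_that("invalid generator configurations name the offending feature", {
  m <- default_marginals()
  m$sd[m$feature == "age"] <- -1
  expect_error(generator_config(marginals = m), "age")
  m2 <- default_marginals()
  m2$p[m2$feature == "diabetes"] <- 1.4
  expect_error(generator_config(marginals = m2), "diabetes")
  expect_error(generator_config(missing_rate = 1), "missing_rate")
  expect_error(
    generator_config(effects = data.frame(feature = "nope",
                                          transform = "linear",
                                          threshold = 0, coef = 1)),
    "nope")
})
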