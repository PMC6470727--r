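test_that("identical configs give byte-identical cohorts", {
  a <- simulate_cohort(sim_config(n_subjects = 1500, seed = 42,
                                  substudy_size = 200))
  b <- simulate_cohort(sim_config(n_subjects = 1500, seed = 42,
                                  substudy_size = 200))
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$substudy, b$substudy)
  expect_identical(a$truth, b$truth)
  c <- simulate_cohort(sim_config(n_subjects = 1500, seed = 43,
                                  substudy_size = 200))
  expect_false(identical(a$cohort, c$cohort))
})

test_that("zero-intake fractions and exposure correlation hit their targets", {
  cfg <- sim_config(n_subjects = 50000, seed = 7)
  tr <- generate_true_exposures(cfg)
  expect_lt(abs(mean(tr$red_true == 0) - 0.646), 0.02)
  expect_lt(abs(mean(tr$processed_true == 0) - 0.667), 0.02)
  r <- cor(tr$red_true, tr$processed_true)
  expect_gte(r, 0.51)
  expect_lte(r, 0.61)
  # default baseline targets ~11% deaths over the accrual/follow-up design
  sv <- generate_survival(tr, cfg)
  expect_lt(abs(mean(sv$event) - 0.11), 0.01)
})

test_that("independent exposures have near-zero empirical correlation", {
  cfg <- sim_config(n_subjects = 10000, seed = 8,
                    exposure_correlation = 0)
  tr <- generate_true_exposures(cfg)
  expect_lt(abs(cor(tr$red_true, tr$processed_true)), 0.05)
})

test_that("infeasible correlation targets fail with a named constraint", {
  # wildly mismatched lognormal tails cap the attainable Pearson r
  cfg <- sim_config(
    n_subjects = 100, seed = 1, exposure_correlation = 0.5,
    exposure_distribution = list(
      red = list(p_zero = 0, mu = 0, sigma = 0.3),
      processed = list(p_zero = 0, mu = 0, sigma = 3),
      poultry = list(p_zero = 0.45, mu = 2.8, sigma = 0.9),
      fish = list(p_zero = 0.40, mu = 2.6, sigma = 0.9)))
  expect_error(generate_true_exposures(cfg), "infeasible correlation")
})

test_that("zero measurement error reproduces true intakes exactly", {
  cfg <- sim_config(n_subjects = 500, seed = 3, substudy_size = 100,
                    ffq_error = c(red = 1e-12, processed = 1e-12,
                                  poultry = 1e-12, fish = 1e-12),
                    recall_error = c(red = 1e-12, processed = 1e-12,
                                     poultry = 1e-12, fish = 1e-12))
  tr <- generate_true_exposures(cfg)
  meas <- generate_ffq_and_recalls(tr, cfg)
  expect_equal(meas$ffq$red_ffq, tr$red_true, tolerance = 1e-9)
  sub_truth <- tr$red_true[meas$substudy$id]
  for (j in 1:6)
    expect_equal(meas$substudy[[paste0("red_recall_", j)]], sub_truth,
                 tolerance = 1e-9)
})

test_that("classical FFQ error at reliability 0.5 attenuates the recall slope", {
  # Gaussian exposure, additive error with equal variance => slope ~ 0.5
  cfg <- sim_config(
    n_subjects = 1000, seed = 21, substudy_size = 1000,
    exposure_distribution = list(
      red = list(p_zero = 0, mu = 10, sigma = 4, family = "normal"),
      processed = list(p_zero = 0, mu = 5, sigma = 2, family = "normal"),
      poultry = list(p_zero = 0, mu = 5, sigma = 2, family = "normal"),
      fish = list(p_zero = 0, mu = 5, sigma = 2, family = "normal")),
    exposure_correlation = 0,
    ffq_error = c(red = 4, processed = 2, poultry = 2, fish = 2),
    recall_error = c(red = 2, processed = 2, poultry = 2, fish = 2))
  tr <- generate_true_exposures(cfg)
  meas <- generate_ffq_and_recalls(tr, cfg)
  slope <- coef(lm(red_recall_mean ~ red_ffq, meas$substudy))[[2]]
  expect_lt(abs(slope - 0.5), 0.08)
})

test_that("conditional Weibull sampling matches the closed-form survivor function", {
  # with all effects zero and no censoring, H0(T) - H0(a) ~ Exp(1)
  cfg <- sim_config(n_subjects = 4000, seed = 13,
                    true_log_hr = c(red = 0),
                    followup_years = 500, admin_censor_age = 1e6,
                    missing_rates = numeric(0))
  tr <- generate_true_exposures(cfg)
  sv <- generate_survival(tr, cfg)
  expect_true(all(sv$event == 1L))
  shp <- 8; scl <- 101
  u <- 1 - exp(-((sv$exit_age / scl)^shp - (sv$entry_age / scl)^shp))
  ks <- suppressWarnings(ks.test(u, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("survival respects left-truncation structure", {
  sim <- simulate_cohort(sim_config(n_subjects = 3000, seed = 17))
  co <- sim$cohort
  expect_true(all(co$exit_age > co$entry_age))
  expect_true(all(co$entry_age >= 25 & co$entry_age <= 90))
  expect_true(all(is.na(co$cause) == (co$event == 0L)))
})

test_that("missingness hits configured rates and is MAR", {
  cfg <- sim_config(n_subjects = 20000, seed = 19,
                    missing_rates = c(bmi = 0.10))
  sim <- simulate_cohort(cfg)
  fr <- mean(is.na(sim$cohort$bmi))
  expect_gte(fr, 0.09)
  expect_lte(fr, 0.11)
  # MAR: given the observed predictors, the held true value carries no
  # information about missingness
  d <- data.frame(mis = is.na(sim$cohort$bmi),
                  true_bmi = sim$truth$bmi,
                  age = sim$cohort$entry_age, sex = sim$cohort$sex)
  fit <- glm(mis ~ true_bmi + age + sex, data = d, family = binomial())
  z <- coef(summary(fit))["true_bmi", "z value"]
  expect_lt(abs(z), 3)
})

test_that("zero missing rates leave the cohort untouched", {
  cfg <- sim_config(n_subjects = 500, seed = 2,
                    missing_rates = c(bmi = 0, education = 0))
  tr <- generate_true_exposures(cfg)
  out <- inject_missingness(tr, cfg)
  attr(out, "miss_mask") <- NULL
  expect_identical(out, tr)
})

test_that("config validation rejects inconsistent settings", {
  expect_error(sim_config(substudy_size = 100, n_subjects = 50),
               "substudy_size")
  expect_error(sim_config(n_recalls = 1), "n_recalls")
  expect_error(sim_config(missing_rates = c(bmi = 1.2)), "missing_rates")
  expect_error(sim_config(exposure_distribution = list(
    red = list(p_zero = 1.1, mu = 1, sigma = 1),
    processed = list(p_zero = 0, mu = 1, sigma = 1),
    poultry = list(p_zero = 0, mu = 1, sigma = 1),
    fish = list(p_zero = 0, mu = 1, sigma = 1))), "zero-inflation")
})
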