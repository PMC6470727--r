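test_that("calibration on error-free data is the identity", {
  cfg <- sim_config(n_subjects = 800, seed = 51, substudy_size = 800,
                    ffq_error = c(red = 1e-12, processed = 1e-12,
                                  poultry = 1e-12, fish = 1e-12),
                    recall_error = c(red = 1e-12, processed = 1e-12,
                                     poultry = 1e-12, fish = 1e-12))
  sim <- simulate_cohort(cfg)
  su <- sim$substudy
  su$red_mod <- log1p(su$red_ffq)
  su$recall_mod <- log1p(su$red_recall_mean)
  cal <- fit_calibration(su, "red_mod", "recall_mod")
  expect_equal(cal$slope, 1, tolerance = 1e-6)
  expect_equal(cal$coefficients[["(Intercept)"]], 0, tolerance = 1e-6)
})

test_that("classical error with reliability 0.5 gives calibration slope ~ 0.5", {
  cfg <- sim_config(
    n_subjects = 1000, seed = 53, substudy_size = 1000,
    exposure_distribution = list(
      red = list(p_zero = 0, mu = 10, sigma = 4, family = "normal"),
      processed = list(p_zero = 0, mu = 5, sigma = 2, family = "normal"),
      poultry = list(p_zero = 0, mu = 5, sigma = 2, family = "normal"),
      fish = list(p_zero = 0, mu = 5, sigma = 2, family = "normal")),
    exposure_correlation = 0,
    ffq_error = c(red = 4, processed = 2, poultry = 2, fish = 2),
    recall_error = c(red = 2, processed = 2, poultry = 2, fish = 2),
    true_log_hr = c(red = 0.02), transform = "identity")
  sim <- simulate_cohort(cfg)
  cal <- fit_calibration(sim$substudy, "red_ffq", "red_recall_mean")
  expect_lt(abs(cal$slope - 0.5), 0.08)
})

test_that("rank-deficient calibration designs are rejected by name", {
  su <- data.frame(f = rnorm(50), r = rnorm(50))
  su$dup <- su$f
  expect_error(fit_calibration(su, "f", "r", covariates = "dup"),
               "collinear")
  expect_error(fit_calibration(su, "f", "r", covariates = "nope"),
               "lacks column")
})

test_that("calibrated predictions follow the fitted linear map", {
  # exact linear relation: recall = 2 + 0.5 * ffq
  su <- data.frame(f = seq(0, 20, length.out = 30))
  su$r <- 2 + 0.5 * su$f
  cal <- fit_calibration(su, "f", "r")
  expect_equal(cal$slope, 0.5, tolerance = 1e-10)
  out <- predict_calibrated(data.frame(f = 10), cal)
  expect_equal(out, 7, tolerance = 1e-10)
  # shrinkage: slope < 1 implies no variance inflation
  co <- data.frame(f = rnorm(200, 10, 3))
  expect_lte(var(predict_calibrated(co, cal)), var(co$f))
  expect_error(predict_calibrated(data.frame(f = c(1, NA)), cal),
               "impute")
})

test_that("rc_cox reduces to the naive fit when calibration is the identity", {
  cfg <- sim_config(n_subjects = 1200, seed = 55, substudy_size = 600,
                    ffq_error = c(red = 1e-12, processed = 1e-12,
                                  poultry = 1e-12, fish = 1e-12),
                    recall_error = c(red = 1e-12, processed = 1e-12,
                                     poultry = 1e-12, fish = 1e-12),
                    missing_rates = numeric(0))
  sim <- simulate_cohort(cfg)
  d <- sim$cohort
  d$red_mod <- log1p(d$red_ffq)
  su <- sim$substudy
  su$red_mod <- log1p(su$red_ffq)
  su$recall_mod <- log1p(su$red_recall_mean)
  r <- rc_cox(survival::Surv(entry_age, exit_age, event) ~ red_mod, d,
              su, "red_mod", "recall_mod", x1 = 46.5)
  expect_equal(r$calibrated$hr, r$naive$hr, tolerance = 1e-6)
  expect_equal(r$calibration$slope, 1, tolerance = 1e-6)
})

test_that("calibration is equivariant under exposure rescaling", {
  set.seed(57)
  n <- 2000
  tr <- rnorm(n, 10, 3)
  d <- data.frame(entry = runif(n, 40, 60))
  death <- d$entry + rexp(n, 0.05 * exp(0.04 * tr))
  cens <- d$entry + runif(n, 2, 25)
  d$exit <- pmin(death, cens); d$status <- as.integer(death <= cens)
  d$w <- tr + rnorm(n, 0, 3)
  su <- data.frame(w = d$w[1:500], r = tr[1:500] + rnorm(500, 0, 1))
  f <- survival::Surv(entry, exit, status) ~ w
  r1 <- rc_cox(f, d, su, "w", "r", x1 = 14, x0 = 4,
               transform = "identity")
  c_ <- 10
  d2 <- transform(d, w = w * c_)
  su2 <- transform(su, w = w * c_)
  # x1/x0 stay on the recall (true-intake) scale, which did not rescale
  r2 <- rc_cox(f, d2, su2, "w", "r", x1 = 14, x0 = 4,
               transform = "identity")
  expect_equal(r2$calibration$slope, r1$calibration$slope / c_,
               tolerance = 1e-8)
  expect_equal(r2$calibrated$hr, r1$calibrated$hr, tolerance = 1e-8)
  # the naive contrast is on the FFQ scale, so its values rescale with it
  nv2 <- contrast_hr(r2$fit_naive, "w", 14 * c_, 4 * c_,
                     transform = "identity")
  expect_equal(nv2$hr, r1$naive$hr, tolerance = 1e-8)
})

test_that("calibrated Cox recovers an attenuated coefficient (beta/slope)", {
  set.seed(59)
  n <- 8000
  tr <- rnorm(n, 10, 4)
  beta <- 0.05
  entry <- runif(n, 45, 60)
  death <- entry + rexp(n, 0.03 * exp(beta * tr))
  cens <- entry + runif(n, 3, 20)
  d <- data.frame(entry = entry, exit = pmin(death, cens),
                  status = as.integer(death <= cens),
                  w = tr + rnorm(n, 0, 4))
  su <- data.frame(w = d$w[1:1000], r = tr[1:1000] + rnorm(1000, 0, 2))
  f <- survival::Surv(entry, exit, status) ~ w
  r <- rc_cox(f, d, su, "w", "r", x1 = 1, x0 = 0,
              transform = "identity")
  b_naive <- log(r$naive$hr)
  b_cal <- log(r$calibrated$hr)
  expect_equal(b_cal, b_naive / r$calibration$slope, tolerance = 1e-6)
  expect_lt(abs(b_cal - beta), 0.015)
  expect_lt(b_naive, 0.8 * beta) # visibly attenuated at reliability 0.5
})

test_that("deattenuation corrects the validity correlation", {
  # no within-person recall noise: observed = deattenuated
  set.seed(61)
  n <- 300
  tr <- rnorm(n)
  ffq <- 0.8 * tr + rnorm(n, 0, 0.6)
  recalls0 <- matrix(rep(tr, 3), ncol = 3)
  r0 <- deattenuate_correlation(ffq, recalls0)
  expect_equal(r0$r_true, r0$r_obs, tolerance = 1e-10)
  # averaging replicates reduces attenuation: a single recall correlates
  # less with the FFQ than the 6-recall mean
  recalls <- tr + matrix(rnorm(n * 6, 0, 1), ncol = 6)
  r6 <- deattenuate_correlation(ffq, recalls)
  expect_lt(cor(ffq, recalls[, 1]), r6$r_obs)
  expect_gt(r6$r_true, r6$r_obs)
  # degenerate recalls with no between-person signal fail
  e <- rnorm(n)
  flat <- cbind(e, -e) # every subject mean is exactly 0
  expect_error(deattenuate_correlation(ffq, flat), "between-person")
})

test_that("deattenuation recovers the generator's configured validity", {
  cfg <- sim_config(
    n_subjects = 1000, seed = 63, substudy_size = 1000,
    exposure_distribution = list(
      red = list(p_zero = 0, mu = 2.5, sigma = 1.0),
      processed = list(p_zero = 0, mu = 0.8, sigma = 1.1),
      poultry = list(p_zero = 0, mu = 2.8, sigma = 0.9),
      fish = list(p_zero = 0, mu = 2.6, sigma = 0.9)),
    ffq_error = c(red = ffq_error_for_validity(0.74, 1.0),
                  processed = ffq_error_for_validity(0.43, 1.1),
                  poultry = 0.5, fish = 0.5))
  sim <- simulate_cohort(cfg)
  su <- sim$substudy
  rec <- log(as.matrix(su[paste0("red_recall_", 1:6)]))
  r <- deattenuate_correlation(log(su$red_ffq), rec)
  expect_lt(abs(r$r_true - 0.74), 0.06)
})
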