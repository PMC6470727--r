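test_that("cox_lt matches the survival package on untied data", {
  for (trunc in c(FALSE, TRUE)) {
    d <- make_lt_data(200, seed = 100 + trunc, truncation = trunc)
    mine <- cox_lt(survival::Surv(entry, exit, status) ~ x + z, d)
    ref <- survival::coxph(survival::Surv(entry, exit, status) ~ x + z, d)
    expect_equal(coef(mine), coef(ref), tolerance = 1e-6)
    expect_equal(sqrt(diag(vcov(mine))), sqrt(diag(vcov(ref))),
                 tolerance = 1e-6)
    expect_equal(mine$loglik[["fitted"]], ref$loglik[2],
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("cox_lt matches the survival package under ties (both methods)", {
  d <- make_lt_data(300, seed = 7)
  d$exit <- round(d$exit) + 0.5 # force heavy ties
  d <- d[d$exit > d$entry, ]
  for (tm in c("efron", "breslow")) {
    mine <- cox_lt(survival::Surv(entry, exit, status) ~ x + z, d,
                   ties = tm)
    ref <- survival::coxph(survival::Surv(entry, exit, status) ~ x + z,
                           d, ties = tm)
    expect_equal(coef(mine), coef(ref), tolerance = 1e-6)
    expect_equal(sqrt(diag(vcov(mine))), sqrt(diag(vcov(ref))),
                 tolerance = 1e-6)
  }
})

test_that("cox_lt agrees with a brute-force grid maximiser on a toy set", {
  d <- data.frame(entry = c(0, 0, 1, 2, 0, 3),
                  exit = c(5, 6, 7, 8, 4.5, 9),
                  status = c(1, 0, 1, 1, 1, 0),
                  x = c(1, 0, 1, 0, 0, 1))
  grid <- seq(-4, 4, by = 1e-4)
  ll <- vapply(grid, brute_partial_loglik, numeric(1),
               entry = d$entry, exit = d$exit, status = d$status, x = d$x)
  beta_grid <- grid[which.max(ll)]
  fit <- cox_lt(survival::Surv(entry, exit, status) ~ x, d)
  expect_lt(abs(coef(fit)[["x"]] - beta_grid), 2e-4)
  expect_equal(fit$loglik[["fitted"]],
               brute_partial_loglik(coef(fit)[["x"]], d$entry, d$exit,
                                    d$status, d$x), tolerance = 1e-10)
})

test_that("coefficients are invariant to covariate shifts and equivariant to scaling", {
  d <- make_lt_data(150, seed = 3)
  f0 <- cox_lt(survival::Surv(entry, exit, status) ~ x + z, d)
  d2 <- transform(d, x = x + 100)
  f1 <- cox_lt(survival::Surv(entry, exit, status) ~ x + z, d2)
  expect_equal(coef(f0), coef(f1), tolerance = 1e-8)
  d3 <- transform(d, x = x * 10)
  f2 <- cox_lt(survival::Surv(entry, exit, status) ~ x + z, d3)
  expect_equal(coef(f2)[["x"]], coef(f0)[["x"]] / 10, tolerance = 1e-8)
})

test_that("subjects entering after the last event never influence the fit", {
  d <- make_lt_data(150, seed = 4)
  last_event <- max(d$exit[d$status == 1])
  extra <- data.frame(entry = last_event + 1,
                      exit = last_event + 5, status = 0L,
                      x = 5, z = 1)
  f0 <- cox_lt(survival::Surv(entry, exit, status) ~ x + z, d)
  f1 <- cox_lt(survival::Surv(entry, exit, status) ~ x + z,
               rbind(d, extra, extra))
  expect_identical(coef(f0), coef(f1))
  expect_identical(vcov(f0), vcov(f1))
})

test_that("ICD-10 classification matches the published ranges exactly", {
  expect_equal(as.character(classify_cause(
    c("I21", "I78", "I79", "C00", "C97", "C98", "V43", "W10", "X60",
      "Y20", "U07", "J18", NA))),
    c("cvd", "cvd", "other_natural", "cancer", "cancer", "other_natural",
      "unnatural_censor", "unnatural_censor", "unnatural_censor",
      "unnatural_censor", "unnatural_censor", "other_natural", NA))
  expect_error(classify_cause("banana"), "malformed")
  # cause-specific censoring: cancer deaths are non-events for CVD etc.
  cc <- classify_cause(c("I21", "C18", "J18", "V43", NA))
  expect_equal(outcome_event(cc, "all_cause"), c(1L, 1L, 1L, 0L, 0L))
  expect_equal(outcome_event(cc, "cvd"), c(1L, 0L, 0L, 0L, 0L))
  expect_equal(outcome_event(cc, "cancer"), c(0L, 1L, 0L, 0L, 0L))
})

test_that("hazard-ratio contrasts follow the delta method and reject degeneracy", {
  d <- make_lt_data(200, seed = 5)
  fit <- cox_lt(survival::Surv(entry, exit, status) ~ x, d)
  expect_error(contrast_hr(fit, "x", 3, 3), "degenerate")
  # constructed inverse: beta = log(1.5)/log1p(46.5) gives HR 1.5 exactly
  m <- structure(list(coefficients = c(meat = log(1.5) / log1p(46.5)),
                      var = matrix(4e-4, dimnames = list("meat", "meat"))),
                 class = "cox_lt")
  ct <- contrast_hr(m, "meat", 46.5, 0)
  expect_equal(ct$hr, 1.5, tolerance = 1e-12)
  expect_true(ct$ci_low <= ct$hr && ct$hr <= ct$ci_high)
  # paper-style 90th percentile inputs give positive spans
  for (x90 in c(46.5, 11, 49.1))
    expect_gt(contrast_hr(m, "meat", x90, 0)$hr, 1)
})

test_that("trend test detects a monotone categorical effect", {
  set.seed(31)
  n <- 6000
  cat5 <- factor(sample(c("zero", "Q1", "Q2", "Q3", "Q4"), n, TRUE),
                 levels = c("zero", "Q1", "Q2", "Q3", "Q4"))
  med <- c(zero = 0, Q1 = 4, Q2 = 9.1, Q3 = 15.6, Q4 = 41.7)
  beta <- log(1.6) / med[["Q4"]]
  entry <- runif(n, 45, 65)
  death <- entry + rexp(n, 0.03 * exp(beta * med[as.character(cat5)]))
  cens <- entry + runif(n, 5, 15)
  d <- data.frame(entry = entry, exit = pmin(death, cens),
                  status = as.integer(death <= cens), cat5 = cat5,
                  z = rnorm(n))
  tr <- trend_test(survival::Surv(entry, exit, status) ~ z, d, "cat5",
                   med)
  expect_lt(tr$p_value, 0.001)
  expect_gt(tr$coef, 0)
})

test_that("rcs basis is a natural cubic spline: continuity and linear tails", {
  knots <- c(1, 3, 6, 10)
  h <- 1e-5
  fd1 <- function(f, x) (f(x + h) - f(x - h)) / (2 * h)
  fd2 <- function(f, x) (f(x + h) - 2 * f(x) + f(x - h)) / h^2
  set.seed(2)
  cf <- rnorm(3)
  f <- function(x) drop(rcs_basis(x, knots = knots) %*% cf)
  for (k in knots) {
    expect_equal(f(k - 1e-9), f(k + 1e-9), tolerance = 1e-6)
    expect_equal(fd1(f, k - 10 * h), fd1(f, k + 10 * h), tolerance = 1e-3)
  }
  # linear beyond the boundary knots: second derivative ~ 0
  expect_lt(abs(fd2(f, 0.2)), 1e-4)
  expect_lt(abs(fd2(f, 12)), 1e-4)
  # curvature present in the interior for a nonzero nonlinear coefficient
  expect_gt(max(abs(vapply(c(4, 7), function(x) fd2(f, x), numeric(1)))),
            1e-3)
  expect_error(rcs_basis(1:30, knots = c(1, 1, 2)), "strictly increasing")
})

test_that("spline nonlinearity test flags a quadratic log-hazard", {
  set.seed(41)
  n <- 6000
  x <- runif(n, 0, 4)
  entry <- runif(n, 45, 65)
  death <- entry + rexp(n, 0.02 * exp(0.25 * (x - 2)^2))
  cens <- entry + runif(n, 5, 15)
  d <- data.frame(entry = entry, exit = pmin(death, cens),
                  status = as.integer(death <= cens), x = x)
  nl <- nonlinearity_test(survival::Surv(entry, exit, status) ~ x, d, "x")
  expect_lt(nl$p_value, 0.01)
  expect_equal(nl$df, 2)
})

test_that("Schoenfeld residuals sum to zero at the MLE and flag non-PH", {
  d <- make_lt_data(400, seed = 6)
  fit <- cox_lt(survival::Surv(entry, exit, status) ~ x + z, d)
  s <- residuals(fit, type = "schoenfeld")
  expect_lt(max(abs(colSums(s))), 1e-5)
  # group-specific Weibull shapes produce a hazard ratio changing with time
  set.seed(61)
  n <- 6000
  grp <- rbinom(n, 1, 0.5)
  t0 <- ifelse(grp == 1, rweibull(n, 0.7, 18), rweibull(n, 1.6, 18))
  cens <- runif(n, 5, 30)
  dn <- data.frame(entry = 0, exit = pmin(t0, cens) + 1e-9 * seq_len(n),
                   status = as.integer(t0 <= cens), grp = grp)
  fitn <- cox_lt(survival::Surv(entry, exit, status) ~ grp, dn)
  ph <- ph_diagnostics(fitn)
  expect_lt(ph$table$p[ph$table$term == "grp"], 1e-4)
  ai <- age_interaction_test(survival::Surv(entry, exit, status) ~ grp,
                             dn, "grp", width = 2)
  expect_lt(ai$p_value, 1e-3)
  # log(-log) plot data are emitted for visual assessment
  ph2 <- ph_diagnostics(fitn, loglog_group = factor(dn$grp))
  expect_true(all(c("time", "cloglog", "group") %in% names(ph2$loglog)))
})

test_that("Wald and LR interaction tests agree to first order at large n", {
  d <- make_lt_data(4000, seed = 8)
  d$sex <- factor(sample(c("F", "M"), nrow(d), TRUE))
  f <- survival::Surv(entry, exit, status) ~ x + sex
  w <- interaction_test(f, d, "x", "sex", test = "wald")
  l <- interaction_test(f, d, "x", "sex", test = "lr")
  expect_equal(w$df, l$df)
  expect_lt(abs(w$p_value - l$p_value), 0.02)
})

test_that("separation and non-variation are reported, not silently fitted", {
  d <- data.frame(entry = 0, exit = c(1, 2, 3, 4, 5, 6),
                  status = c(1, 1, 1, 0, 0, 0), x = c(1, 1, 1, 0, 0, 0))
  expect_error(cox_lt(survival::Surv(entry, exit, status) ~ x, d),
               "separation|monotone")
  d2 <- transform(d, x = 1)
  expect_error(cox_lt(survival::Surv(entry, exit, status) ~ x, d2),
               "constant")
})
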