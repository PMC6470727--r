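#' Fit a regression-calibration model on the recall substudy
#'
#' Ordinary least squares of the reference measure (mean of the 24-h recall
#' replicates, or their median) on the error-prone FFQ measure plus the
#' analytic covariates, fitted on the substudy rows only. The fitted model
#' maps an FFQ value (and covariates) to the expected recall intake; its
#' predictions are the calibrated exposures used by [predict_calibrated()]
#' and [rc_cox()]. All variables are taken on the modelled (transformed)
#' scale chosen by the caller.
#'
#' @param substudy data frame containing `exposure`, `recall` and
#'   `covariates` columns.
#' @param exposure name of the FFQ exposure column.
#' @param recall name of the recall summary column (e.g. the replicate
#'   mean).
#' @param covariates character vector of covariate column names (the
#'   covariates of the analytic model being calibrated).
#' @return object of class `calibration_model`: coefficients, residual
#'   variance, n, and the fitted `lm`.
#' @export
fit_calibration <- function(substudy, exposure, recall,
                            covariates = character()) {
  miss <- setdiff(c(exposure, recall, covariates), names(substudy))
  if (length(miss))
    stop("substudy lacks column(s): ", paste(miss, collapse = ", "))
  f <- as.formula(paste(recall, "~", paste(c(exposure, covariates),
                                           collapse = " + ")))
  fit <- lm(f, data = substudy)
  if (any(is.na(coef(fit)))) {
    dropped <- names(coef(fit))[is.na(coef(fit))]
    stop("rank-deficient calibration design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  structure(list(coefficients = coef(fit),
                 slope = coef(fit)[[exposure]],
                 sigma2 = sum(residuals(fit)^2) / fit$df.residual,
                 n = nrow(substudy), exposure = exposure, recall = recall,
                 covariates = covariates, lm = fit),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, digits = 4, ...) {
  cat("Calibration model (n =", x$n, "):", x$recall, "~", x$exposure,
      if (length(x$covariates)) paste("+", length(x$covariates),
                                      "covariate(s)") else "", "\n")
  cat("  slope on", x$exposure, "=", round(x$slope, digits),
      "; residual variance =", round(x$sigma2, digits), "\n")
  invisible(x)
}

#' Predict calibrated exposures for the main cohort
#'
#' Applies a fitted [fit_calibration()] model to every cohort row,
#' returning the predicted (expected recall) exposure. When the calibration
#' slope is below 1 the calibrated column is shrunk, i.e. has no larger
#' variance than the FFQ column. Covariates must be complete: run
#' imputation first.
#'
#' @param cohort data frame with the FFQ exposure and all calibration
#'   covariates.
#' @param model a `calibration_model`.
#' @return numeric vector of calibrated exposure values.
#' @export
predict_calibrated <- function(cohort, model) {
  need <- c(model$exposure, model$covariates)
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort lacks column(s): ", paste(miss, collapse = ", "))
  nas <- vapply(cohort[need], anyNA, logical(1))
  if (any(nas))
    stop("missing values in ", paste(need[nas], collapse = ", "),
         "; impute covariates before calibration")
  unname(predict(model$lm, newdata = cohort))
}

#' Regression-calibrated Cox hazard-ratio contrast
#'
#' The flagship two-stage estimator: (1) fit the calibration model on the
#' substudy ([fit_calibration()]), controlling for the covariates of the
#' analytic model; (2) replace the FFQ exposure by its calibrated
#' prediction in the cohort; (3) fit the left-truncated Cox model
#' ([cox_lt()]); (4) report the hazard ratio for the `x1` vs `x0` contrast
#' (typically the 90th percentile of intake vs zero) on the modelled scale.
#' The naive (uncalibrated) fit and contrast are always computed alongside.
#' Because classical measurement error attenuates the naive log hazard
#' ratio by roughly the calibration slope, the calibrated hazard ratio is
#' farther from 1 whenever the slope is below 1.
#'
#' Optionally a BCa bootstrap ([bootstrap_bca()]) of the whole two-stage
#' procedure — resampling cohort and substudy subjects independently and,
#' by default, refitting the calibration model in every replicate — gives
#' the calibrated confidence interval; otherwise a Wald interval from the
#' second-stage model is reported (which ignores first-stage uncertainty).
#'
#' @param formula Cox formula; the right-hand side must contain
#'   `exposure_term`, a column of `data` holding the transformed FFQ
#'   exposure.
#' @param data cohort data frame (complete covariates).
#' @param substudy calibration substudy containing the same exposure
#'   column and `recall_term`.
#' @param exposure_term name of the transformed FFQ exposure column.
#' @param recall_term name of the transformed recall-summary column in
#'   `substudy`.
#' @param x1,x0 contrast values on the original g/day scale.
#' @param transform transform linking g/day to the modelled scale
#'   (`"log1p"` default); must be the transform already applied to
#'   `exposure_term` and `recall_term`.
#' @param ties passed to [cox_lt()].
#' @param boot `NULL` for Wald intervals, or a list of options for the BCa
#'   bootstrap: `B` (replicates, default 4000), `seed`,
#'   `refit_calibration` (default `TRUE`; `FALSE` holds stage-1
#'   coefficients fixed), `jackknife` (`"grouped"` default, or `"loo"`),
#'   `groups` (jackknife group count, default 50).
#' @param level confidence level.
#' @return object of class `rc_cox`: the naive and calibrated
#'   [contrast_hr()] results, the calibration model, both Cox fits, and
#'   the bootstrap result when requested.
#' @export
rc_cox <- function(formula, data, substudy, exposure_term, recall_term,
                   x1, x0 = 0, transform = "log1p", ties = "efron",
                   boot = NULL, level = 0.95) {
  covars <- setdiff(all.vars(formula[[3]]), exposure_term)
  cal <- fit_calibration(substudy, exposure_term, recall_term,
                         intersect(covars, names(substudy)))
  fit_naive <- cox_lt(formula, data, ties = ties)
  data_cal <- data
  data_cal[[exposure_term]] <- predict_calibrated(data, cal)
  fit_cal <- cox_lt(formula, data_cal, ties = ties)
  naive <- contrast_hr(fit_naive, exposure_term, x1, x0, transform, level)
  calibrated <- contrast_hr(fit_cal, exposure_term, x1, x0, transform,
                            level)
  out <- list(naive = naive, calibrated = calibrated, calibration = cal,
              fit_naive = fit_naive, fit_calibrated = fit_cal,
              x1 = x1, x0 = x0, transform = transform, level = level)
  if (!is.null(boot)) {
    B <- boot$B %||% 4000L
    refit <- boot$refit_calibration %||% TRUE
    g <- exposure_transform(transform)
    span <- g(x1) - g(x0)
    stat <- function(tables) {
      co <- tables$cohort; su <- tables$substudy
      cm <- if (refit)
        fit_calibration(su, exposure_term, recall_term,
                        intersect(covars, names(su)))
      else cal
      co[[exposure_term]] <- predict_calibrated(co, cm)
      f <- cox_lt(formula, co, ties = ties)
      coef(f)[[exposure_term]] * span
    }
    br <- bootstrap_bca(stat,
                        list(cohort = data, substudy = substudy),
                        B = B, alpha = 1 - level,
                        seed = boot$seed %||% 1L,
                        jackknife = boot$jackknife %||% "grouped",
                        groups = boot$groups %||% 50L)
    out$boot <- br
    out$calibrated$ci_low <- exp(br$ci_low)
    out$calibrated$ci_high <- exp(br$ci_high)
    out$calibrated$p_value <-
      2 * pnorm(-abs(br$t0 / sd(br$replicates)))
  }
  class(out) <- "rc_cox"
  out
}

#' @export
print.rc_cox <- function(x, ...) {
  cat("Regression-calibrated Cox contrast (", x$x1, "vs", x$x0,
      "g/day,", x$transform, "scale)\n")
  cat("  calibration slope:", round(x$calibration$slope, 3),
      "(substudy n =", x$calibration$n, ")\n")
  cat("  naive:      "); print(x$naive)
  cat("  calibrated: "); print(x$calibrated)
  if (!is.null(x$boot))
    cat("  (calibrated CI: BCa bootstrap, B =", length(x$boot$replicates),
        ")\n")
  invisible(x)
}

#' Deattenuated validity correlation from replicate recalls
#'
#' The crude correlation between the FFQ and the mean of `k` recall
#' replicates understates the FFQ--usual-intake correlation because the
#' replicate mean still carries within-person variance. With the
#' within/between variance ratio `lambda` estimated by one-way ANOVA
#' components on the replicates, the deattenuated validity correlation is
#' `r_true = r_obs * sqrt(1 + lambda / k)`, clipped to [-1, 1] with a
#' warning if exceeded.
#'
#' @param ffq numeric vector of FFQ values (one per subject), on the scale
#'   on which the error is approximately classical (e.g. log intake).
#' @param recalls numeric matrix, one row per subject and one column per
#'   replicate, same scale.
#' @return list with `r_true`, `r_obs`, `lambda`, `k`.
#' @export
deattenuate_correlation <- function(ffq, recalls) {
  recalls <- as.matrix(recalls)
  k <- ncol(recalls)
  if (k < 2) stop("need >= 2 recall replicates per subject")
  n <- nrow(recalls)
  if (length(ffq) != n) stop("ffq and recalls dimensions differ")
  subj_means <- rowMeans(recalls)
  grand <- mean(recalls)
  msb <- k * sum((subj_means - grand)^2) / (n - 1)
  msw <- sum((recalls - subj_means)^2) / (n * (k - 1))
  sigma2_b <- (msb - msw) / k
  if (sigma2_b <= 0)
    stop("non-positive between-person variance; no usable signal in the ",
         "recalls")
  lambda <- msw / sigma2_b
  r_obs <- cor(ffq, subj_means)
  r_true <- r_obs * sqrt(1 + lambda / k)
  if (abs(r_true) > 1) {
    warning("deattenuated correlation exceeded |1|; clipped")
    r_true <- sign(r_true)
  }
  list(r_true = r_true, r_obs = r_obs, lambda = lambda, k = k)
}
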