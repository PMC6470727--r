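#' Classify an ICD-10 cause-of-death code into analysis outcomes
#'
#' Cause-specific mortality outcomes follow the ICD-10 ranges used in the
#' cohort analysis: cardiovascular deaths are codes I00--I78, cancer deaths
#' C00--C97, and deaths from unnatural causes (codes beginning U, V, W, X or
#' Y, e.g. motor-vehicle accidents, homicides) are censored at the death age
#' for every outcome including all-cause mortality. All other codes are
#' natural deaths counted for all-cause mortality only.
#'
#' @param code character vector of ICD-10 codes (letter followed by digits,
#'   e.g. `"I21"`, `"C18"`); `NA` is returned as `NA` (no death).
#' @return factor with levels `"cvd"`, `"cancer"`, `"other_natural"`,
#'   `"unnatural_censor"`.
#' @examples
#' classify_cause(c("I21", "I78", "I79", "C97", "C98", "V43", "J18"))
#' @export
classify_cause <- function(code) {
  out <- rep(NA_character_, length(code))
  ok <- !is.na(code)
  cc <- toupper(trimws(code[ok]))
  bad <- !grepl("^[A-Z][0-9]{2}", cc)
  if (any(bad))
    stop("malformed ICD-10 code(s) at row(s) ",
         paste(which(ok)[bad], collapse = ", "), ": ",
         paste(unique(cc[bad]), collapse = ", "))
  letter <- substr(cc, 1, 1)
  num <- as.integer(substr(cc, 2, 3))
  cls <- rep("other_natural", length(cc))
  cls[letter == "I" & num <= 78] <- "cvd"
  cls[letter == "C" & num <= 97] <- "cancer"
  cls[letter %in% c("U", "V", "W", "X", "Y")] <- "unnatural_censor"
  out[ok] <- cls
  factor(out, levels = c("cvd", "cancer", "other_natural",
                         "unnatural_censor"))
}

#' Event indicator for a cause-specific (or all-cause) outcome
#'
#' Deaths from other natural causes are censored at the death age for the
#' cause-specific outcomes; unnatural deaths are censored for every outcome.
#'
#' @param cause factor from [classify_cause()] (NA = alive/censored).
#' @param outcome `"all_cause"`, `"cvd"` or `"cancer"`.
#' @return integer 0/1 event vector.
#' @export
outcome_event <- function(cause,
                          outcome = c("all_cause", "cvd", "cancer")) {
  outcome <- match.arg(outcome)
  ev <- switch(outcome,
    all_cause = !is.na(cause) & cause != "unnatural_censor",
    cvd = !is.na(cause) & cause == "cvd",
    cancer = !is.na(cause) & cause == "cancer")
  as.integer(ev)
}

#' Hazard ratio for a contrast of two exposure values
#'
#' Computes `HR = exp(beta * (g(x1) - g(x0)))` for a model term, with a Wald
#' confidence interval by the delta method on the linear-predictor
#' difference. The typical use is the contrast of the 90th percentile of
#' intake against zero intake, with `g = log1p` so that zero intake is a
#' valid reference (`log1p(0) = 0`).
#'
#' @param model a fitted [cox_lt()] object (or anything with `coef`/`vcov`).
#' @param term name of the coefficient.
#' @param x1,x0 exposure values on the original (g/day) scale.
#' @param transform `"log1p"` (default), `"identity"`, or a function; the
#'   transform must match the scale the model term was fitted on.
#' @param level confidence level.
#' @return object of class `hr_contrast`: list with `hr`, `ci_low`,
#'   `ci_high`, `p_value`, `log_hr`, `se_log_hr`, `contrast`.
#' @examples
#' # beta chosen so that the 46.5 vs 0 contrast is exactly HR = 1.5
#' b <- log(1.5) / log1p(46.5)
#' m <- list(coefficients = c(meat = b),
#'           var = matrix(1e-4, dimnames = list("meat", "meat")))
#' class(m) <- "cox_lt"
#' contrast_hr(m, "meat", 46.5, 0)
#' @export
contrast_hr <- function(model, term, x1, x0, transform = "log1p",
                        level = 0.95) {
  g <- exposure_transform(transform)
  if (isTRUE(all.equal(g(x1), g(x0))))
    stop("degenerate contrast: g(x1) == g(x0)")
  cf <- coef(model)
  if (!term %in% names(cf)) stop("term not in model: ", term)
  span <- g(x1) - g(x0)
  est <- cf[[term]] * span
  se <- sqrt(vcov(model)[term, term]) * abs(span)
  z <- qnorm(1 - (1 - level) / 2)
  structure(list(
    hr = exp(est), ci_low = exp(est - z * se), ci_high = exp(est + z * se),
    p_value = 2 * pnorm(-abs(est / se)), log_hr = est, se_log_hr = se,
    level = level,
    contrast = sprintf("%s: %g vs %g (transform %s)", term, x1, x0,
                       if (is.character(transform)) transform else "custom")),
    class = "hr_contrast")
}

#' @export
print.hr_contrast <- function(x, digits = 3, ...) {
  cat(sprintf("HR %.*f (%.0f%% CI %.*f-%.*f), p = %.2g  [%s]\n", digits,
              x$hr, 100 * x$level, digits, x$ci_low, digits, x$ci_high,
              x$p_value, x$contrast))
  invisible(x)
}

exposure_transform <- function(transform) {
  if (is.function(transform)) return(transform)
  switch(transform,
         log1p = log1p,
         identity = identity,
         log = log,
         stop("unknown transform: ", transform))
}

#' Trend test across ordered exposure categories
#'
#' Implements the standard epidemiological trend test: every subject is
#' assigned the median intake of their category (the zero-intake category
#' scores its median, 0), and the model is refitted with this single
#' continuous score in place of the category indicators. The Wald p-value of
#' the score coefficient is the trend p.
#'
#' @param formula Cox formula for the adjustment covariates (the exposure
#'   itself must not appear; e.g. `Surv(entry, exit, ev) ~ sex + energy`).
#' @param data data frame.
#' @param category factor (or column name in `data`) of exposure categories.
#' @param medians named numeric of per-category median intakes, names
#'   matching `levels(category)`.
#' @param ties passed to [cox_lt()].
#' @return list with `p_value`, `coef`, `se`, `fit`.
#' @export
trend_test <- function(formula, data, category, medians, ties = "efron") {
  if (is.character(category) && length(category) == 1L)
    category <- data[[category]]
  category <- as.factor(category)
  if (!all(levels(category) %in% names(medians)))
    stop("medians must be named for every category level")
  data$.trend_score <- as.numeric(medians[as.character(category)])
  f2 <- update(formula, . ~ . + .trend_score)
  fit <- cox_lt(f2, data, ties = ties)
  b <- coef(fit)[[".trend_score"]]
  se <- sqrt(vcov(fit)[".trend_score", ".trend_score"])
  list(p_value = 2 * pnorm(-abs(b / se)), coef = b, se = se, fit = fit)
}

#' Restricted cubic spline basis
#'
#' Natural (restricted) cubic spline basis in the truncated-power
#' parameterisation: the first column is `x` itself and the remaining
#' `k - 2` columns are the nonlinear components, constrained to be linear
#' beyond the boundary knots and scaled by the squared knot span for
#' conditioning. With this parameterisation a test that all columns beyond
#' the first are zero is a test of nonlinearity.
#'
#' @param x numeric vector.
#' @param knots knot locations (strictly increasing); default placement is
#'   at the 5/35/65/95 percentiles of `x` for `n_knots = 4`.
#' @param n_knots number of knots when `knots` is `NULL`.
#' @return matrix with `length(knots) - 1` columns and attribute `"knots"`.
#' @export
rcs_basis <- function(x, knots = NULL, n_knots = 4) {
  if (is.null(knots)) {
    probs <- switch(as.character(n_knots),
                    "3" = c(.1, .5, .9),
                    "4" = c(.05, .35, .65, .95),
                    "5" = c(.05, .275, .5, .725, .95),
                    seq(.05, .95, length.out = n_knots))
    knots <- unique(quantile(x, probs, names = FALSE, type = 7))
  }
  if (length(knots) < 3) stop("need at least 3 distinct knots")
  if (is.unsorted(knots, strictly = TRUE))
    stop("knots must be strictly increasing")
  k <- length(knots)
  tau2 <- (knots[k] - knots[1])^2
  p3 <- function(u) pmax(u, 0)^3
  B <- matrix(0, length(x), k - 1)
  B[, 1] <- x
  for (j in seq_len(k - 2)) {
    B[, j + 1] <- (p3(x - knots[j]) -
      p3(x - knots[k - 1]) * (knots[k] - knots[j]) /
        (knots[k] - knots[k - 1]) +
      p3(x - knots[k]) * (knots[k - 1] - knots[j]) /
        (knots[k] - knots[k - 1])) / tau2
  }
  colnames(B) <- c("lin", paste0("nl", seq_len(k - 2)))
  attr(B, "knots") <- knots
  B
}

#' Wald test of nonlinearity via a restricted cubic spline
#'
#' Refits the model with `term` expanded into a 4-knot restricted cubic
#' spline and tests (Wald) that the coefficients of all nonlinear basis
#' columns are zero.
#'
#' @param formula Cox formula including `term` linearly.
#' @param data data frame.
#' @param term name of the continuous exposure column.
#' @param knots,n_knots passed to [rcs_basis()]; default knots are placed on
#'   the distribution of `data[[term]]`.
#' @param ties passed to [cox_lt()].
#' @return list with `p_value`, `chisq`, `df`, `fit`, `knots`.
#' @export
nonlinearity_test <- function(formula, data, term, knots = NULL,
                              n_knots = 4, ties = "efron") {
  x <- data[[term]]
  if (length(unique(x)) < 20)
    stop("need >= 20 distinct values of ", term, " for a spline fit")
  B <- rcs_basis(x, knots = knots, n_knots = n_knots)
  nl <- colnames(B)[-1]
  for (j in colnames(B)) data[[paste0(".rcs_", j)]] <- B[, j]
  f2 <- update(formula,
    as.formula(paste(". ~ . -", term, "+",
                     paste(paste0(".rcs_", colnames(B)), collapse = "+"))))
  fit <- cox_lt(f2, data, ties = ties)
  idx <- paste0(".rcs_", nl)
  b <- coef(fit)[idx]
  V <- vcov(fit)[idx, idx, drop = FALSE]
  stat <- drop(t(b) %*% solve(V, b))
  list(p_value = pchisq(stat, df = length(b), lower.tail = FALSE),
       chisq = stat, df = length(b), fit = fit,
       knots = attr(B, "knots"))
}

#' Proportional-hazards diagnostics
#'
#' Per-term Grambsch--Therneau test of the proportional-hazards assumption:
#' the correlation of the scaled Schoenfeld residuals with a transform of
#' event age. The per-term chi-square (1 df) is
#' `[sum (g_k - gbar) s_k]' (d * Vbar * sum (g_k - gbar)^2)^{-1} [...]`
#' with `Vbar = I(beta)/d`, the classic score form. Optionally also returns
#' the data for log(-log) survival plots of a grouping variable
#' (Kaplan--Meier via the survival package; visual check only, not
#' auto-judged).
#'
#' @param fit a [cox_lt()] fit.
#' @param transform transform of event age for the test: `"identity"`
#'   (default), `"log"`, `"rank"`, or a function.
#' @param loglog_group optional factor (same length as the fitting data)
#'   for log(-log) plot data.
#' @param data data frame used to fit the model (only needed with
#'   `loglog_group` given as a column name).
#' @return list with `table` (data frame: term, chisq, df, p), `global`
#'   (global test), and optionally `loglog` (data frame of time,
#'   -log(-log(S)), group).
#' @export
ph_diagnostics <- function(fit, transform = "identity",
                           loglog_group = NULL, data = NULL) {
  s <- residuals(fit, type = "schoenfeld")
  times <- attr(s, "time")
  gfun <- if (is.function(transform)) transform else
    switch(transform, identity = identity, log = log,
           rank = function(t) rank(t), stop("unknown transform"))
  g <- gfun(times)
  gc <- g - mean(g)
  d <- nrow(s)
  Vbar <- solve(fit$var) / d # average per-event information
  u <- drop(crossprod(gc, s))            # sum (g - gbar) s_k
  denom <- sum(gc^2)
  # score test for beta(t) = beta + theta * g(t): Var(U) ~ sum(gc^2) * Vbar
  chisq <- u^2 / (denom * diag(Vbar))
  tab <- data.frame(term = colnames(s), chisq = chisq, df = 1,
                    p = pchisq(chisq, 1, lower.tail = FALSE),
                    row.names = NULL)
  gstat <- drop(t(u) %*% solve(Vbar * denom, u))
  out <- list(table = tab,
              global = list(chisq = gstat, df = ncol(s),
                            p = pchisq(gstat, ncol(s), lower.tail = FALSE)))
  if (!is.null(loglog_group)) {
    dc <- fit$data_cache
    if (is.character(loglog_group) && length(loglog_group) == 1L) {
      stopifnot(!is.null(data))
      loglog_group <- data[[loglog_group]]
    }
    sf <- survival::survfit(
      survival::Surv(dc$entry, dc$exit, dc$status) ~ grp,
      data = data.frame(grp = loglog_group))
    keep <- sf$surv > 0 & sf$surv < 1
    out$loglog <- data.frame(
      time = sf$time[keep],
      cloglog = log(-log(sf$surv[keep])),
      group = rep(sub("^grp=", "", names(sf$strata)), sf$strata)[keep])
  }
  out
}

#' Interaction (effect-modification) test
#'
#' Tests the product term(s) `exposure x modifier` by a Wald (default) or
#' likelihood-ratio test comparing the model with and without the product.
#'
#' @param formula Cox formula containing both main effects.
#' @param data data frame.
#' @param exposure,modifier term names.
#' @param test `"wald"` or `"lr"`.
#' @param ties passed to [cox_lt()].
#' @return list with `p_value`, `stat`, `df`, `fit`.
#' @export
interaction_test <- function(formula, data, exposure, modifier,
                             test = c("wald", "lr"), ties = "efron") {
  test <- match.arg(test)
  if (is.factor(data[[modifier]]) && nlevels(droplevels(data[[modifier]])) < 2)
    stop("modifier does not vary")
  f2 <- update(formula, as.formula(
    paste(". ~ . +", exposure, ":", modifier)))
  fit2 <- cox_lt(f2, data, ties = ties)
  inter <- grep(":", names(coef(fit2)), value = TRUE)
  inter <- inter[grepl(exposure, inter, fixed = TRUE)]
  if (length(inter) == 0L) stop("no interaction terms produced")
  if (test == "wald") {
    b <- coef(fit2)[inter]
    V <- vcov(fit2)[inter, inter, drop = FALSE]
    stat <- drop(t(b) %*% solve(V, b))
    df <- length(b)
  } else {
    fit1 <- cox_lt(formula, data, ties = ties)
    stat <- 2 * (fit2$loglik[["fitted"]] - fit1$loglik[["fitted"]])
    df <- length(coef(fit2)) - length(coef(fit1))
  }
  list(p_value = pchisq(stat, df, lower.tail = FALSE), stat = stat,
       df = df, fit = fit2)
}

#' Split follow-up into episodes on the age axis
#'
#' Splits each subject's at-risk interval `(entry, exit]` at a grid of ages,
#' producing counting-process episodes (the partial likelihood is invariant
#' to such splitting). Used to approximate time-varying terms such as
#' covariate-by-log(age) interactions.
#'
#' @param data data frame with entry/exit/status columns.
#' @param entry,exit,status column names.
#' @param cuts numeric vector of ages to split at.
#' @return data frame of episodes with the same covariate columns and an
#'   added `.age_mid` column (midpoint age of the episode).
#' @export
split_episodes <- function(data, entry = "entry", exit = "exit",
                           status = "status", cuts) {
  cuts <- sort(unique(cuts))
  out <- vector("list", nrow(data))
  en <- data[[entry]]; ex <- data[[exit]]; st <- data[[status]]
  for (i in seq_len(nrow(data))) {
    brk <- c(en[i], cuts[cuts > en[i] & cuts < ex[i]], ex[i])
    m <- length(brk) - 1L
    rows <- data[rep(i, m), , drop = FALSE]
    rows[[entry]] <- brk[-length(brk)]
    rows[[exit]] <- brk[-1]
    rows[[status]] <- c(rep(0L, m - 1L), st[i])
    rows$.age_mid <- (brk[-length(brk)] + brk[-1]) / 2
    out[[i]] <- rows
  }
  do.call(rbind, out)
}

#' Attained-age interaction check of proportional hazards
#'
#' Refits the model with an added `term x log(attained age)` product,
#' approximated by splitting follow-up into 1-year episodes on the age axis
#' so that the product is evaluated at the episode age. A small Wald p-value
#' indicates a hazard ratio that changes with age (a proportional-hazards
#' violation).
#'
#' @param formula Cox formula containing `term`.
#' @param data data frame with entry/exit/status columns named in the
#'   formula response.
#' @param term covariate whose age interaction is tested.
#' @param width episode width in years (default 1).
#' @param ties passed to [cox_lt()].
#' @return list with `p_value`, `coef`, `se`, `fit`.
#' @export
age_interaction_test <- function(formula, data, term, width = 1,
                                 ties = "efron") {
  resp <- all.vars(formula[[2]])
  if (length(resp) != 3L)
    stop("formula response must be Surv(entry, exit, status)")
  rng <- range(data[[resp[1]]], data[[resp[2]]])
  cuts <- seq(floor(rng[1]), ceiling(rng[2]), by = width)
  ep <- split_episodes(data, resp[1], resp[2], resp[3], cuts)
  ep$.x_logage <- ep[[term]] * log(ep$.age_mid)
  f2 <- update(formula, . ~ . + .x_logage)
  fit <- cox_lt(f2, ep, ties = ties)
  b <- coef(fit)[[".x_logage"]]
  se <- sqrt(vcov(fit)[".x_logage", ".x_logage"])
  list(p_value = 2 * pnorm(-abs(b / se)), coef = b, se = se, fit = fit)
}
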