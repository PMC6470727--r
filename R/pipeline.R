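#' Analysis specification for the full study grid
#'
#' Defines the exposure x outcome x model grid and the analysis options.
#' The three model tiers are nested covariate sets: model 1 adjusts for
#' sex, race and total energy (age is the time scale); model 2 adds the
#' lifestyle and clinical covariates; model 3 additionally adjusts for the
#' other meat variables — for the unprocessed-red exposure the processed
#' exposure and vice versa, plus poultry and fish, while the combined
#' red + processed exposure is never mutually adjusted for its own
#' components. Cancer-mortality models 2 and 3 additionally adjust for
#' previous cancer screening.
#'
#' @param exposures subset of `c("red", "processed", "combined")`.
#' @param outcomes subset of `c("all_cause", "cvd", "cancer")`.
#' @param models named list of covariate-column vectors; defaults build
#'   the nested tiers from the synthetic-cohort column dictionary.
#' @param transform modelled exposure scale (`"log1p"` default: defined at
#'   zero intake, log-like for large intakes).
#' @param quartile_basis `"consumers"` or `"total"`, see
#'   [categorize_exposure()].
#' @param m imputations for missing covariates.
#' @param B BCa bootstrap rounds for the calibrated interval (0 disables
#'   the bootstrap; the reference analysis uses 4000).
#' @param bca_cells character vector of `"exposure:outcome"` cells that
#'   get the bootstrap interval (bootstrap cost is per cell).
#' @param calibrate logical: run the regression-calibration branch.
#' @param seed master seed for imputation and bootstrap.
#' @return list of class `analysis_spec`.
#' @export
analysis_spec <- function(
    exposures = c("red", "processed", "combined"),
    outcomes = c("all_cause", "cvd", "cancer"),
    models = NULL,
    transform = "log1p",
    quartile_basis = "consumers",
    m = 5L, B = 0L,
    bca_cells = "combined:all_cause",
    calibrate = TRUE,
    seed = 1L) {
  exposures <- match.arg(exposures, several.ok = TRUE)
  outcomes <- match.arg(outcomes, several.ok = TRUE)
  if (is.null(models)) {
    m1 <- c("sex", "race", "energy")
    m2 <- c(m1, "marital", "education", "smoking", "exercise", "bmi")
    models <- list(model1 = m1, model2 = m2, model3 = m2)
    # model-3 meat adjustments are exposure-specific, added at run time
  }
  for (i in seq_along(models)[-1])
    if (!all(models[[i - 1]] %in% models[[i]]))
      stop("model tiers must be nested (model", i, " must contain model",
           i - 1, ")")
  structure(list(exposures = exposures, outcomes = outcomes,
                 models = models, transform = transform,
                 quartile_basis = quartile_basis, m = as.integer(m),
                 B = as.integer(B), bca_cells = bca_cells,
                 calibrate = isTRUE(calibrate), seed = as.integer(seed)),
            class = "analysis_spec")
}

# exposure-specific model-3 meat adjustment terms (modelled-scale columns)
model3_extras <- function(exposure) {
  switch(exposure,
         red = c("processed_mod", "poultry_mod", "fish_mod"),
         processed = c("red_mod", "poultry_mod", "fish_mod"),
         combined = c("poultry_mod", "fish_mod"))
}

#' Run the full study analysis grid
#'
#' Orchestrates the complete pipeline on an analysis cohort and its
#' calibration substudy: cause-of-death classification, residual-method
#' energy adjustment, zero + consumer-quartile categorisation, multiple
#' imputation of missing covariates, and — per exposure x outcome x model
#' cell — Rubin-pooled quartile hazard ratios, the trend test over
#' quartile medians, the continuous 90th-percentile-vs-zero contrast
#' (uncalibrated), and the regression-calibrated contrast with an optional
#' BCa bootstrap interval. Substudy subjects are matched to cohort rows by
#' `id` so the calibration model can control for the analytic covariates.
#' Population attributable risk for the combined exposure is computed from
#' the exposed fraction at/above the 90th percentile. Deterministic given
#' the spec seed.
#'
#' A failing cell is recorded with its error message and the remaining
#' cells proceed; the report always contains one entry per grid cell.
#'
#' @param cohort analysis cohort (columns: id, entry_age, exit_age, event,
#'   cause, FFQ intakes `red_ffq`/`processed_ffq`/`combined_ffq`/
#'   `poultry_ffq`/`fish_ffq`, energy, covariates).
#' @param substudy calibration substudy (id, FFQ values, recall means).
#' @param spec an [analysis_spec()].
#' @return object of class `study_report`: list with `cells` (per-cell
#'   results), `par`, `categorisation`, `exclusions`, `n`, `events`,
#'   `provenance`.
#' @export
run_full_analysis <- function(cohort, substudy, spec = analysis_spec()) {
  stopifnot(inherits(spec, "analysis_spec"))
  g <- exposure_transform(spec$transform)

  excl <- apply_exclusions(cohort)
  cohort <- excl$cohort

  cause <- classify_cause(cohort$cause)
  for (oc in c("all_cause", "cvd", "cancer"))
    cohort[[paste0("ev_", oc)]] <- outcome_event(cause, oc)

  # energy-adjusted g/day for categorisation and percentile contrasts;
  # modelled-scale columns for the continuous fits (energy is a model
  # covariate, so the fitted exposure coefficient is invariant to residual
  # adjustment of the exposure itself)
  exposures_all <- c("red", "processed", "combined", "poultry", "fish")
  categorisation <- list()
  for (e in exposures_all) {
    ffq <- cohort[[paste0(e, "_ffq")]]
    cohort[[paste0(e, "_adj")]] <- residual_energy_adjust(ffq,
                                                          cohort$energy)
    cohort[[paste0(e, "_mod")]] <- g(ffq)
  }
  for (e in spec$exposures) {
    adj <- cohort[[paste0(e, "_adj")]]
    raw <- cohort[[paste0(e, "_ffq")]]
    # zero group = true zero reporters; quartile cuts on the adjusted scale
    cons <- raw > 0
    cuts <- quantile(if (spec$quartile_basis == "consumers") adj[cons]
                     else adj, c(.25, .5, .75), names = FALSE)
    lev <- c("zero", "Q1", "Q2", "Q3", "Q4")
    cat_ <- factor(rep("zero", nrow(cohort)), levels = lev)
    cat_[cons] <- lev[findInterval(adj[cons], cuts,
                                   left.open = TRUE) + 2L]
    cohort[[paste0(e, "_cat")]] <- cat_
    meds <- vapply(lev, function(l)
      if (l == "zero") 0 else median(raw[cat_ == l]), numeric(1))
    x90 <- quantile(adj, 0.9, names = FALSE)
    categorisation[[e]] <- list(medians = meds, cutpoints = cuts,
                                x90 = x90,
                                zero_fraction = mean(!cons))
  }

  imp_preds <- unique(c(unlist(spec$models), "entry_age", "ev_all_cause",
                        paste0(spec$exposures, "_mod")))
  imp <- impute_cohort(cohort, m = spec$m,
                       seed = stream_seed(spec$seed, "pipeline"),
                       predictors = intersect(imp_preds, names(cohort)))
  sub_cov <- function(d) {
    keep <- intersect(names(substudy), names(d))
    merge(substudy, d[setdiff(names(d), setdiff(keep, "id"))], by = "id")
  }

  cells <- list()
  for (e in spec$exposures) for (oc in spec$outcomes)
    for (mt in names(spec$models)) {
      key <- paste(e, oc, mt, sep = ":")
      cells[[key]] <- tryCatch(
        run_cell(imp, substudy, spec, e, oc, mt, categorisation[[e]],
                 sub_cov),
        error = function(err)
          list(failed = TRUE, error = conditionMessage(err)))
    }

  par <- list()
  if ("combined" %in% spec$exposures) {
    x90 <- categorisation$combined$x90
    pfrac <- mean(cohort$combined_adj >= x90)
    for (oc in intersect(c("all_cause", "cvd"), spec$outcomes)) {
      cell <- cells[[paste("combined", oc,
                           tail(names(spec$models), 1), sep = ":")]]
      if (!isTRUE(cell$failed)) {
        hr <- if (!is.null(cell$calibrated)) cell$calibrated$hr else
          cell$continuous$hr
        par[[oc]] <- population_attributable_risk(hr, pfrac)
      }
    }
    attr(par, "exposed_fraction") <- pfrac
  }

  structure(list(cells = cells, par = par,
                 categorisation = categorisation,
                 exclusions = excl$ledger,
                 n = nrow(cohort),
                 events = vapply(paste0("ev_",
                                        c("all_cause", "cvd", "cancer")),
                                 function(v) sum(cohort[[v]]),
                                 numeric(1)),
                 provenance = list(seed = spec$seed, m = spec$m,
                                   B = spec$B,
                                   transform = spec$transform,
                                   spec_hash = spec_hash(spec))),
            class = "study_report")
}

run_cell <- function(imp, substudy, spec, exposure, outcome, mtier,
                     catinfo, sub_cov) {
  covars <- spec$models[[mtier]]
  if (mtier == tail(names(spec$models), 1))
    covars <- c(covars, model3_extras(exposure))
  if (outcome == "cancer" && mtier != names(spec$models)[1])
    covars <- union(covars, "screening")
  resp <- sprintf("survival::Surv(entry_age, exit_age, ev_%s)", outcome)
  catcol <- paste0(exposure, "_cat")
  modcol <- paste0(exposure, "_mod")
  g <- exposure_transform(spec$transform)
  x90 <- catinfo$x90
  span <- g(x90) - g(0)

  m <- length(imp$imputations)
  est_cat <- vector("list", m); var_cat <- vector("list", m)
  est_tr <- numeric(m); var_tr <- numeric(m)
  est_co <- numeric(m); var_co <- numeric(m)
  est_cal <- numeric(m); var_cal <- numeric(m)
  nevent <- NA_integer_
  for (i in seq_len(m)) {
    d <- imp$imputations[[i]]
    fcat <- as.formula(paste(resp, "~", catcol, "+",
                             paste(covars, collapse = "+")))
    fit <- cox_lt(fcat, d)
    nevent <- fit$nevent
    qterms <- paste0(catcol, c("Q1", "Q2", "Q3", "Q4"))
    est_cat[[i]] <- coef(fit)[qterms]
    var_cat[[i]] <- diag(vcov(fit))[qterms]
    fadj <- as.formula(paste(resp, "~", paste(covars, collapse = "+")))
    tr <- trend_test(fadj, d, d[[catcol]], catinfo$medians)
    est_tr[i] <- tr$coef; var_tr[i] <- tr$se^2
    fcont <- as.formula(paste(resp, "~", modcol, "+",
                              paste(covars, collapse = "+")))
    fitc <- cox_lt(fcont, d)
    est_co[i] <- coef(fitc)[[modcol]]
    var_co[i] <- vcov(fitc)[modcol, modcol]
    if (spec$calibrate) {
      su <- sub_cov(d)
      su[[modcol]] <- g(su[[paste0(exposure, "_ffq")]])
      su$.recall_mod <- g(su[[paste0(exposure, "_recall_mean")]])
      cal <- fit_calibration(su, modcol, ".recall_mod",
                             intersect(covars, names(su)))
      dcal <- d
      dcal[[modcol]] <- predict_calibrated(d, cal)
      fitk <- cox_lt(fcont, dcal)
      est_cal[i] <- coef(fitk)[[modcol]]
      var_cal[i] <- vcov(fitk)[modcol, modcol]
    }
  }
  pool_contrast <- function(est, vr) {
    pe <- rubin_pool(matrix(est, ncol = 1,
                            dimnames = list(NULL, "beta")),
                     matrix(vr, ncol = 1,
                            dimnames = list(NULL, "beta")))
    row <- pe$table[1, ]
    list(hr = exp(row$estimate * span),
         ci_low = exp(row$ci_low * span), ci_high = exp(row$ci_high * span),
         p_value = row$p, log_hr = row$estimate * span,
         se_log_hr = row$se * span)
  }
  qpool <- rubin_pool(do.call(rbind, est_cat), do.call(rbind, var_cat))
  trpool <- rubin_pool(matrix(est_tr, ncol = 1,
                              dimnames = list(NULL, "trend")),
                       matrix(var_tr, ncol = 1,
                              dimnames = list(NULL, "trend")))
  out <- list(
    exposure = exposure, outcome = outcome, model = mtier,
    n_events = nevent, x90 = x90,
    quartiles = within(qpool$table, {
      hr <- exp(estimate); hr_low <- exp(ci_low); hr_high <- exp(ci_high)
    }),
    trend_p = trpool$table$p[1],
    continuous = pool_contrast(est_co, var_co))
  if (spec$calibrate) {
    out$calibrated <- pool_contrast(est_cal, var_cal)
    key <- paste(exposure, outcome, sep = ":")
    if (spec$B > 0 && key %in% spec$bca_cells) {
      d1 <- imp$imputations[[1]]
      fcont <- as.formula(paste(resp, "~", modcol, "+",
                                paste(covars, collapse = "+")))
      br <- rc_cox(fcont, d1, {
        su <- sub_cov(d1)
        su[[modcol]] <- g(su[[paste0(exposure, "_ffq")]])
        su$.recall_mod <- g(su[[paste0(exposure, "_recall_mean")]])
        su
      }, modcol, ".recall_mod", x1 = x90, x0 = 0,
      transform = spec$transform,
      boot = list(B = spec$B, seed = stream_seed(spec$seed, "boot")))
      out$calibrated_bca <- list(hr = br$calibrated$hr,
                                 ci_low = br$calibrated$ci_low,
                                 ci_high = br$calibrated$ci_high,
                                 B = length(br$boot$replicates),
                                 z0 = br$boot$z0, a = br$boot$a)
    }
  }
  out
}

spec_hash <- function(spec) {
  s <- paste(deparse(unclass(spec)), collapse = "")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' @export
print.study_report <- function(x, digits = 2, ...) {
  cat("Study report: n =", x$n, "; events:",
      paste(names(x$events), x$events, collapse = ", "), "\n")
  for (key in names(x$cells)) {
    cell <- x$cells[[key]]
    if (isTRUE(cell$failed)) {
      cat(sprintf("  %-28s FAILED: %s\n", key, cell$error)); next
    }
    line <- sprintf("  %-28s 90th-vs-0 HR %.2f (%.2f-%.2f)", key,
                    cell$continuous$hr, cell$continuous$ci_low,
                    cell$continuous$ci_high)
    if (!is.null(cell$calibrated))
      line <- paste0(line, sprintf("; calibrated %.2f (%.2f-%.2f)",
                                   cell$calibrated$hr,
                                   cell$calibrated$ci_low,
                                   cell$calibrated$ci_high))
    cat(line, "\n")
  }
  if (length(x$par)) {
    for (oc in names(x$par))
      cat(sprintf("  PAR (%s): %.1f%%\n", oc, 100 * x$par[[oc]]))
  }
  invisible(x)
}

#' Subgroup analysis with stratum-specific contrasts
#'
#' Refits the continuous 90th-vs-zero contrast within each level of the
#' subgroup axis (sex or race), using stratum-specific 90th percentiles of
#' the energy-adjusted intake, and attaches the interaction p-value from
#' the full-cohort product-term test. Strata with fewer than 30 events are
#' flagged `low_information` rather than dropped.
#'
#' @param cohort complete-covariate analysis cohort (e.g. one imputation),
#'   with `ev_<outcome>` event columns already present or a `cause` column
#'   to classify.
#' @param spec an [analysis_spec()].
#' @param axis subgroup column name (`"sex"` or `"race"`).
#' @param exposure,outcome single exposure/outcome for the table.
#' @return data frame: stratum, n, events, x90, hr, ci_low, ci_high,
#'   low_information, plus attribute `"interaction_p"`.
#' @export
subgroup_analysis <- function(cohort, spec, axis, exposure = "combined",
                              outcome = "all_cause") {
  g <- exposure_transform(spec$transform)
  if (!paste0("ev_", outcome) %in% names(cohort))
    cohort[[paste0("ev_", outcome)]] <-
      outcome_event(classify_cause(cohort$cause), outcome)
  modcol <- paste0(exposure, "_mod")
  if (!modcol %in% names(cohort))
    cohort[[modcol]] <- g(cohort[[paste0(exposure, "_ffq")]])
  adjcol <- paste0(exposure, "_adj")
  if (!adjcol %in% names(cohort))
    cohort[[adjcol]] <- residual_energy_adjust(
      cohort[[paste0(exposure, "_ffq")]], cohort$energy)
  covars <- setdiff(spec$models[[length(spec$models)]], axis)
  resp <- sprintf("survival::Surv(entry_age, exit_age, ev_%s)", outcome)
  f <- as.formula(paste(resp, "~", modcol, "+",
                        paste(covars, collapse = "+")))
  full_f <- as.formula(paste(resp, "~", modcol, "+",
                             paste(union(covars, axis), collapse = "+")))
  ip <- tryCatch(interaction_test(full_f, cohort, modcol, axis)$p_value,
                 error = function(e) NA_real_)
  rows <- lapply(levels(droplevels(as.factor(cohort[[axis]]))),
                 function(lv) {
    d <- cohort[cohort[[axis]] == lv, , drop = FALSE]
    x90 <- quantile(d[[adjcol]], 0.9, names = FALSE)
    ev <- sum(d[[paste0("ev_", outcome)]])
    ct <- tryCatch({
      fit <- cox_lt(f, d)
      contrast_hr(fit, modcol, g(x90), 0, transform = "identity")
    }, error = function(e) list(hr = NA_real_, ci_low = NA_real_,
                                ci_high = NA_real_))
    data.frame(stratum = lv, n = nrow(d), events = ev, x90 = x90,
               hr = ct$hr, ci_low = ct$ci_low, ci_high = ct$ci_high,
               low_information = ev < 30 || is.na(ct$hr))
  })
  out <- do.call(rbind, rows)
  attr(out, "interaction_p") <- ip
  out
}

#' Never-smoker sensitivity analysis
#'
#' Restricts the cohort (and its substudy rows) to subjects who report
#' never having smoked and reruns the main analysis grid with the smoking
#' covariate dropped, to probe residual confounding by smoking. Row counts
#' in and out are recorded in the returned report's provenance.
#'
#' @param cohort,substudy as in [run_full_analysis()].
#' @param spec an [analysis_spec()].
#' @param never_level level of the smoking column meaning never smoked.
#' @return a `study_report` for the never-smoker subset.
#' @export
never_smoker_sensitivity <- function(cohort, substudy,
                                     spec = analysis_spec(),
                                     never_level = "never") {
  keep <- !is.na(cohort$smoking) & cohort$smoking == never_level
  sub <- cohort[keep, , drop = FALSE]
  spec$models <- lapply(spec$models, setdiff, y = "smoking")
  rep_ <- run_full_analysis(sub, substudy[substudy$id %in% sub$id, ,
                                          drop = FALSE], spec)
  rep_$provenance$subset <- list(filter = paste("smoking ==", never_level),
                                 n_in = nrow(cohort), n_out = nrow(sub))
  rep_
}

#' Population attributable risk (Levin's formula)
#'
#' `PAR = p (HR - 1) / (1 + p (HR - 1))` where `p` is the fraction of the
#' population at or above the contrast exposure (assuming causality). PAR
#' is monotone increasing in both arguments and 0 at HR = 1.
#'
#' @param hr hazard ratio (> 0) of the contrast.
#' @param exposed_fraction fraction exposed, in (0, 1).
#' @return attributable fraction in (-Inf, 1).
#' @examples
#' population_attributable_risk(1.5, 0.1)  # 0.1 * 0.5 / 1.05 = 0.04762
#' @export
population_attributable_risk <- function(hr, exposed_fraction) {
  stopifnot(hr > 0, exposed_fraction > 0, exposed_fraction < 1)
  exposed_fraction * (hr - 1) / (1 + exposed_fraction * (hr - 1))
}

#' Descriptive baseline table by exposure category
#'
#' Per exposure category, reports n and one row per requested
#' characteristic: `n (%)` for a factor level, `mean (SD)` or median for a
#' numeric column. Percentage denominators can be restricted to women
#' (e.g. for menopause-related rows).
#'
#' @param cohort data frame.
#' @param category factor of exposure categories.
#' @param characteristics named list; each element is
#'   `list(var =, stat = "mean_sd"|"n_pct"|"median", level =, women_only
#'   = FALSE)` (`level` only for `"n_pct"`).
#' @return data frame, one row per characteristic, one column per
#'   category, plus an `n` header row.
#' @export
baseline_table <- function(cohort, category, characteristics) {
  category <- as.factor(category)
  lev <- levels(category)
  fmt_cell <- function(d, ch) {
    v <- d[[ch$var]]
    switch(ch$stat,
      mean_sd = sprintf("%.1f (%.1f)", mean(v, na.rm = TRUE),
                        sd(v, na.rm = TRUE)),
      median = sprintf("%.1f", median(v, na.rm = TRUE)),
      n_pct = {
        if (isTRUE(ch$women_only)) {
          d <- d[d$sex == "F", , drop = FALSE]
          v <- d[[ch$var]]
        }
        k <- sum(v == ch$level, na.rm = TRUE)
        sprintf("%d (%.1f)", k, 100 * k / sum(!is.na(v)))
      },
      stop("unknown stat: ", ch$stat))
  }
  rows <- lapply(names(characteristics), function(nm) {
    ch <- characteristics[[nm]]
    cells <- vapply(lev, function(l)
      fmt_cell(cohort[category == l, , drop = FALSE], ch), character(1))
    data.frame(characteristic = nm, t(cells), check.names = FALSE)
  })
  header <- data.frame(characteristic = "n",
                       t(vapply(lev, function(l)
                         as.character(sum(category == l)), character(1))),
                       check.names = FALSE)
  out <- rbind(header, do.call(rbind, rows))
  names(out) <- c("characteristic", lev)
  rownames(out) <- NULL
  out
}
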