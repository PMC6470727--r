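#' Multiple imputation of covariates by chained equations
#'
#' Fills missing covariate cells by fully conditional specification:
#' continuous variables by Bayesian linear regression with
#' predictive-mean-matching (PMM, k donors), categorical variables by
#' logistic (2 levels) or multinomial (more levels) draws with bootstrap
#' weights for properness. Only covariates may be imputed; exposures,
#' entry/exit ages and events must be complete. Non-missing cells are never
#' altered, and the `m` completed tables are identical to the input
#' wherever it was observed. Deterministic given `seed`.
#'
#' @param data data frame.
#' @param m number of imputations (default 5).
#' @param seed RNG seed.
#' @param predictors character vector of predictor columns; defaults to
#'   every column except the `exclude` set.
#' @param exclude columns never imputed (and excluded from the default
#'   predictor set): identifiers and survival bookkeeping columns such as
#'   the cause-of-death code, which is structurally missing for survivors.
#' @param maxit chained-equation sweeps per imputation (default 5).
#' @param pmm_k donor pool size for PMM (default 5).
#' @return object of class `imputed_set`: list with `imputations` (list of
#'   `m` completed data frames), `m`, `seed`, `method` (per-variable), and
#'   `miss_fraction`.
#' @export
impute_cohort <- function(data, m = 5L, seed = 1L, predictors = NULL,
                          exclude = c("id", "cause", "entry_age",
                                      "exit_age", "event"),
                          maxit = 5L, pmm_k = 5L) {
  stopifnot(m >= 2L)
  targets <- setdiff(names(data)[vapply(data, anyNA, logical(1))],
                     exclude)
  if (length(targets) == 0L) {
    return(structure(list(imputations = rep(list(data), m), m = m,
                          seed = seed, method = character(0),
                          miss_fraction = numeric(0)),
                     class = "imputed_set"))
  }
  mf <- vapply(data[targets], function(x) mean(is.na(x)), numeric(1))
  if (any(mf >= 1)) stop("column(s) entirely missing: ",
                         paste(targets[mf >= 1], collapse = ", "))
  if (any(mf > 0.5))
    warning("column(s) more than 50% missing: ",
            paste(targets[mf > 0.5], collapse = ", "))
  if (is.null(predictors)) predictors <- setdiff(names(data), exclude)
  targets <- targets[order(mf)]
  method <- vapply(data[targets], function(x)
    if (is.numeric(x) && length(unique(na.omit(x))) > 10) "pmm"
    else if (is.numeric(x) && length(unique(na.omit(x))) <= 2) "logreg"
    else if (is.factor(x) && nlevels(x) == 2) "logreg"
    else "polyreg", character(1))

  imps <- vector("list", m)
  for (i in seq_len(m)) {
    imps[[i]] <- with_seed(stream_seed(seed, "impute") + i,
                           impute_once(data, targets, predictors, method,
                                       maxit, pmm_k))
  }
  structure(list(imputations = imps, m = m, seed = seed, method = method,
                 miss_fraction = mf), class = "imputed_set")
}

impute_once <- function(data, targets, predictors, method, maxit, pmm_k) {
  d <- data
  na_idx <- lapply(targets, function(v) which(is.na(d[[v]])))
  names(na_idx) <- targets
  # initial fill: random draws from the observed values
  for (v in targets) {
    obs <- d[[v]][!is.na(d[[v]])]
    d[[v]][na_idx[[v]]] <- sample(obs, length(na_idx[[v]]),
                                  replace = TRUE)
  }
  for (it in seq_len(maxit)) {
    for (v in targets) {
      mis <- na_idx[[v]]
      if (length(mis) == 0L) next
      preds <- setdiff(predictors, v)
      X <- model.matrix(
        as.formula(paste("~", paste(preds, collapse = "+"))), d)
      yfull <- data[[v]]
      obs <- which(!is.na(yfull))
      d[[v]][mis] <- switch(method[[v]],
        pmm = impute_pmm(yfull[obs], X[obs, , drop = FALSE],
                         X[mis, , drop = FALSE], pmm_k),
        logreg = impute_logreg(yfull[obs], X[obs, , drop = FALSE],
                               X[mis, , drop = FALSE]),
        polyreg = impute_polyreg(d[[v]], yfull, obs, d, preds, mis))
    }
  }
  d
}

# Bayesian linear regression draw + predictive-mean matching (type-1)
impute_pmm <- function(y_obs, X_obs, X_mis, k) {
  qrx <- qr(X_obs)
  keep <- qrx$pivot[seq_len(qrx$rank)]
  X_obs <- X_obs[, keep, drop = FALSE]
  X_mis <- X_mis[, keep, drop = FALSE]
  fit <- lm.fit(X_obs, y_obs)
  betahat <- fit$coefficients
  res <- fit$residuals
  df <- length(y_obs) - ncol(X_obs)
  sigma2 <- sum(res^2) / rchisq(1, df)
  XtXinv <- chol2inv(chol(crossprod(X_obs) +
                            diag(1e-8, ncol(X_obs))))
  beta_draw <- betahat + drop(chol(XtXinv) %*% rnorm(ncol(X_obs))) *
    sqrt(sigma2)
  pred_obs <- drop(X_obs %*% betahat)
  pred_mis <- drop(X_mis %*% beta_draw)
  ord <- order(pred_obs)
  po <- pred_obs[ord]; yo <- y_obs[ord]
  n_obs <- length(po)
  vapply(pred_mis, function(p) {
    pos <- findInterval(p, po)
    lo <- max(1L, pos - k); hi <- min(n_obs, pos + k)
    cand <- lo:hi
    cand <- cand[order(abs(po[cand] - p))][seq_len(min(k, length(cand)))]
    yo[cand[sample.int(length(cand), 1L)]]
  }, numeric(1))
}

# logistic draw with bootstrap weights (keeps all factor levels)
impute_logreg <- function(y_obs, X_obs, X_mis) {
  lev <- if (is.factor(y_obs)) levels(y_obs) else sort(unique(y_obs))
  y01 <- if (is.factor(y_obs)) as.integer(y_obs == lev[2]) else
    as.integer(y_obs == lev[2])
  w <- tabulate(sample.int(length(y01), replace = TRUE), length(y01))
  fit <- suppressWarnings(
    glm.fit(X_obs, y01, weights = w + 1e-6, family = binomial()))
  p <- plogis(drop(X_mis %*% fit$coefficients))
  draw <- rbinom(length(p), 1, p)
  if (is.factor(y_obs)) factor(lev[draw + 1L], levels = lev) else
    lev[draw + 1L]
}

# multinomial draw with bootstrap weights
impute_polyreg <- function(y_cur, y_full, obs, d, preds, mis) {
  dd <- d[obs, c(preds), drop = FALSE]
  dd$.y <- droplevels(as.factor(y_full[obs]))
  w <- tabulate(sample.int(nrow(dd), replace = TRUE), nrow(dd))
  fit <- suppressWarnings(nnet::multinom(
    as.formula(paste(".y ~", paste(preds, collapse = "+"))),
    data = dd, weights = w + 1e-6, trace = FALSE, maxit = 200))
  pr <- predict(fit, newdata = d[mis, preds, drop = FALSE],
                type = "probs")
  lev <- levels(dd$.y)
  if (is.null(dim(pr))) {
    # single missing row (>2 levels) or 2-level fit return a bare vector
    pr <- if (length(lev) == 2L) cbind(1 - pr, pr) else
      matrix(pr, nrow = 1L)
  }
  draws <- apply(pr, 1L, function(p) sample(lev, 1L, prob = p))
  factor(draws, levels = levels(as.factor(y_full)))
}

#' @export
print.imputed_set <- function(x, ...) {
  cat("Multiply imputed set: m =", x$m, "\n")
  if (length(x$miss_fraction)) {
    cat("  imputed columns (missing fraction):\n")
    for (v in names(x$miss_fraction))
      cat("   ", v, sprintf("(%.1f%%, %s)\n", 100 * x$miss_fraction[[v]],
                            x$method[[v]]))
  } else cat("  no missing cells; copies of the input\n")
  invisible(x)
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Pooled estimate = mean of the per-imputation estimates; total variance
#' `T = W + (1 + 1/m) B` with `W` the mean within-imputation variance and
#' `B` the between-imputation variance; degrees of freedom by Rubin's
#' small-sample formula `(m - 1)(1 + W / ((1 + 1/m) B))^2`; confidence
#' intervals from the t distribution. For ratio estimates (hazard ratios)
#' pool on the log scale and exponentiate afterwards.
#'
#' @param estimates an `m x p` matrix (or list of equally named vectors)
#'   of per-imputation point estimates.
#' @param variances list of `m` covariance matrices, or an `m x p` matrix
#'   of squared standard errors.
#' @param level confidence level.
#' @return object of class `pooled_estimate`: data frame `table` with
#'   estimate, se, df, CI and p per term, plus `W`, `B`, `T`, `m`.
#' @examples
#' rubin_pool(rbind(c(b = 1.0), c(b = 1.2)),
#'            rbind(c(b = 0.04), c(b = 0.04)))
#' @export
rubin_pool <- function(estimates, variances, level = 0.95) {
  if (is.list(estimates) && !is.data.frame(estimates))
    estimates <- do.call(rbind, estimates)
  estimates <- as.matrix(estimates)
  m <- nrow(estimates)
  if (m < 2L) stop("need m >= 2 imputations to pool")
  if (is.list(variances)) {
    vnames <- lapply(variances, function(v)
      if (is.matrix(v)) colnames(v) else names(v))
    variances <- do.call(rbind, lapply(variances, function(v)
      if (is.matrix(v)) diag(v) else v))
    if (!is.null(vnames[[1]])) colnames(variances) <- vnames[[1]]
  }
  variances <- as.matrix(variances)
  if (!identical(dim(estimates), dim(variances)))
    stop("estimates and variances dimensions differ")
  if (!is.null(colnames(estimates)) && !is.null(colnames(variances)) &&
      !identical(colnames(estimates), colnames(variances)))
    stop("mismatched term sets across imputations")
  qbar <- colMeans(estimates)
  W <- colMeans(variances)
  B <- apply(estimates, 2L, var)
  Tv <- W + (1 + 1 / m) * B
  df <- ifelse(B > 0, (m - 1) * (1 + W / ((1 + 1 / m) * B))^2, Inf)
  se <- sqrt(Tv)
  tq <- qt(1 - (1 - level) / 2, df)
  tab <- data.frame(term = colnames(estimates) %||%
                      paste0("b", seq_along(qbar)),
                    estimate = qbar, se = se, df = df,
                    ci_low = qbar - tq * se, ci_high = qbar + tq * se,
                    p = 2 * pt(-abs(qbar / se), df), row.names = NULL)
  structure(list(table = tab, W = W, B = B, T = Tv, m = m, level = level),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, digits = 4, ...) {
  cat("Rubin-pooled estimates over m =", x$m, "imputations\n")
  print(cbind(x$table[1], round(x$table[-1], digits)))
  invisible(x)
}
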