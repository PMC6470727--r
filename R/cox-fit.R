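#' Cox proportional hazards with left truncation on the attained-age scale
#'
#' Fits a Cox proportional-hazards model by Newton--Raphson maximisation of
#' the left-truncated partial likelihood. The response is a
#' [survival::Surv()] object, either `Surv(time, status)` (entry at 0) or
#' the counting-process form `Surv(entry, exit, status)` used for the
#' attained-age time scale, where a subject is at risk only on
#' `(entry, exit]`. The risk set at an event age `t` is
#' `{i : entry_i < t <= exit_i}`.
#'
#' Tied event times are handled by the Efron approximation by default
#' (Breslow selectable), the accepted default for age-scale data with
#' coarsely recorded ages. The covariance matrix is the inverse of the
#' observed information at the maximum.
#'
#' @param formula model formula with a `survival::Surv` response.
#' @param data data frame containing the model variables.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param init optional starting coefficient vector.
#' @param control list with elements `max_iter` (default 30), `grad_tol`
#'   (convergence when the max absolute score component falls below it,
#'   default 1e-9) and `coef_max` (absolute coefficient bound beyond which a
#'   monotone likelihood / separation error is raised, default 12 on the
#'   internally standardised scale).
#' @return an object of class `cox_lt` with components `coefficients`,
#'   `var` (covariance matrix), `loglik` (null and fitted log partial
#'   likelihood), `score_norm`, `n`, `nevent`, `iter`, `ties`, `formula`,
#'   and the model frame metadata needed by `predict` and `residuals`.
#' @examples
#' d <- data.frame(entry = c(0, 0, 1, 1, 2), exit = c(5, 6, 7, 4, 8),
#'                 status = c(1, 0, 1, 1, 0), x = c(1, 0, 1, 0, 1))
#' fit <- cox_lt(survival::Surv(entry, exit, status) ~ x, d)
#' coef(fit)
#' @seealso [contrast_hr()], [trend_test()], [ph_diagnostics()]
#' @export
cox_lt <- function(formula, data, ties = c("efron", "breslow"), init = NULL,
                   control = list()) {
  ties <- match.arg(ties)
  ctrl <- list(max_iter = 30L, grad_tol = 1e-9, coef_max = 12)
  ctrl[names(control)] <- control

  mf <- model.frame(formula, data = data, na.action = na.omit)
  y <- model.response(mf)
  if (!inherits(y, "Surv")) stop("response must be a survival::Surv object")
  ytype <- attr(y, "type")
  if (ytype == "right") {
    entry <- rep(0, nrow(y)); exit <- y[, 1L]; status <- y[, 2L]
  } else if (ytype == "counting") {
    entry <- y[, 1L]; exit <- y[, 2L]; status <- y[, 3L]
  } else stop("unsupported Surv type: ", ytype)
  if (any(exit <= entry)) stop("all exit times must exceed entry times")
  nevent <- sum(status == 1)
  if (nevent < 1L) stop("no events in the data")
  # subjects entering at/after the last event age never join a risk set;
  # dropping them up front makes the fit invariant to their presence
  n_total <- length(entry)
  keep_rows <- entry < max(exit[status == 1])
  entry <- entry[keep_rows]; exit <- exit[keep_rows]
  status <- status[keep_rows]

  mt <- attr(mf, "terms")
  X <- model.matrix(mt, mf)
  xassign <- attr(X, "assign")
  keep <- xassign != 0L
  X <- X[keep_rows, keep, drop = FALSE]
  if (ncol(X) == 0L) stop("model has no covariates")
  xnames <- colnames(X)

  # centre and scale for a well-conditioned Newton step; undone afterwards
  xbar <- colMeans(X)
  xsd <- apply(X, 2L, sd)
  if (any(xsd == 0))
    stop("covariate(s) constant in the data: ",
         paste(xnames[xsd == 0], collapse = ", "))
  Xs <- sweep(sweep(X, 2L, xbar), 2L, xsd, "/")

  beta <- if (is.null(init)) rep(0, ncol(X)) else as.numeric(init) * xsd
  efron <- ties == "efron"
  st <- as.integer(status)

  pl <- cox_pl_cpp(beta, entry, exit, st, Xs, efron)
  loglik0 <- cox_pl_cpp(rep(0, ncol(X)), entry, exit, st, Xs, efron)$loglik
  iter <- 0L
  converged <- FALSE
  # the partial loglik is evaluated to rounding noise that grows with n, so
  # convergence uses the Newton decrement g'H^{-1}g (the expected loglik
  # gain) relative to the loglik magnitude, with one polishing step taken
  # after it falls below tolerance (quadratic convergence makes the
  # remaining coefficient error negligible)
  repeat {
    g <- pl$grad
    if (max(abs(g)) < ctrl$grad_tol || iter >= ctrl$max_iter) {
      converged <- max(abs(g)) < ctrl$grad_tol
      break
    }
    step <- tryCatch(solve(pl$imat, g), error = function(e)
      stop("singular information matrix; check for collinear covariates"))
    decrement <- sum(step * g)
    halves <- 0L
    stalled <- FALSE
    repeat {
      cand <- beta + step
      pl2 <- cox_pl_cpp(cand, entry, exit, st, Xs, efron)
      if (is.finite(pl2$loglik) && pl2$loglik >= pl$loglik - 1e-9) break
      step <- step / 2
      halves <- halves + 1L
      if (halves > 20L) {
        # flat to rounding error: accept if the expected gain is trivial
        if (decrement < 1e-4 * (abs(pl$loglik) + 1) * 1e-3) {
          stalled <- TRUE; break
        }
        stop("step halving failed; last gradient norm ",
             format(max(abs(g))))
      }
    }
    if (stalled) { converged <- TRUE; break }
    beta <- cand; pl <- pl2; iter <- iter + 1L
    if (any(abs(beta) > ctrl$coef_max))
      stop("monotone likelihood (possible separation): |coef| > ",
           ctrl$coef_max, " on the standardised scale")
    if (decrement < 1e-9 * (abs(pl$loglik) + 1)) { converged <- TRUE; break }
  }
  if (!converged)
    stop("Newton-Raphson did not converge in ", ctrl$max_iter,
         " iterations; last gradient norm ", format(max(abs(pl$grad))))

  vs <- solve(pl$imat)
  coefs <- beta / xsd
  V <- diag(1 / xsd, length(xsd)) %*% vs %*% diag(1 / xsd, length(xsd))
  dimnames(V) <- list(xnames, xnames)
  names(coefs) <- xnames

  structure(list(
    coefficients = coefs, var = V,
    loglik = c(null = loglik0, fitted = pl$loglik),
    score_norm = max(abs(pl$grad)), n = n_total, nevent = nevent,
    iter = iter, ties = ties, formula = formula, terms = mt,
    xlevels = .getXlevels(mt, mf), means = xbar,
    data_cache = list(entry = entry, exit = exit, status = st, X = X),
    call = match.call()), class = "cox_lt")
}

#' @export
print.cox_lt <- function(x, digits = 4, ...) {
  cat("Left-truncated Cox model (", x$ties, " ties), n = ", x$n,
      ", events = ", x$nevent, "\n", sep = "")
  print(round(cbind(coef = coef(x), `exp(coef)` = exp(coef(x)),
                    se = sqrt(diag(x$var))), digits))
  invisible(x)
}

#' @export
coef.cox_lt <- function(object, ...) object$coefficients

#' @export
vcov.cox_lt <- function(object, ...) object$var

#' @export
logLik.cox_lt <- function(object, ...) {
  structure(object$loglik[["fitted"]], df = length(object$coefficients),
            class = "logLik")
}

#' @export
confint.cox_lt <- function(object, parm, level = 0.95, ...) {
  cf <- coef(object); se <- sqrt(diag(object$var))
  z <- qnorm(1 - (1 - level) / 2)
  ci <- cbind(cf - z * se, cf + z * se)
  colnames(ci) <- paste(round(100 * c((1 - level) / 2, 1 - (1 - level) / 2),
                              1), "%")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
summary.cox_lt <- function(object, ...) {
  cf <- coef(object); se <- sqrt(diag(object$var))
  z <- cf / se
  tab <- cbind(coef = cf, `exp(coef)` = exp(cf), `se(coef)` = se, z = z,
               `Pr(>|z|)` = 2 * pnorm(-abs(z)))
  structure(list(coefficients = tab, n = object$n, nevent = object$nevent,
                 loglik = object$loglik, ties = object$ties,
                 call = object$call), class = "summary.cox_lt")
}

#' @export
print.summary.cox_lt <- function(x, ...) {
  cat("n =", x$n, ", events =", x$nevent, "; ties =", x$ties, "\n")
  printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat("Log partial likelihood: null", format(x$loglik[["null"]]),
      "fitted", format(x$loglik[["fitted"]]), "\n")
  invisible(x)
}

#' @export
predict.cox_lt <- function(object, newdata = NULL,
                           type = c("lp", "risk"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    X <- object$data_cache$X
  } else {
    tt <- delete.response(object$terms)
    mf <- model.frame(tt, newdata, xlev = object$xlevels)
    X <- model.matrix(tt, mf)
    X <- X[, names(coef(object)), drop = FALSE]
  }
  lp <- drop(sweep(X, 2L, object$means) %*% coef(object))
  if (type == "risk") exp(lp) else lp
}

#' Residuals for `cox_lt` fits
#'
#' `type = "schoenfeld"` returns the matrix of (unscaled) Schoenfeld
#' residuals, one row per event in ascending event-age order, with the event
#' ages as attribute `"time"`. At the MLE the residuals of each term sum to
#' (numerically) zero. `type = "scaled_schoenfeld"` returns the
#' Grambsch--Therneau scaled version `d * V^{-1} s_k + beta`.
#'
#' @param object a `cox_lt` fit.
#' @param type residual type.
#' @param ... unused.
#' @export
residuals.cox_lt <- function(object,
                             type = c("schoenfeld", "scaled_schoenfeld"),
                             ...) {
  type <- match.arg(type)
  dc <- object$data_cache
  xsd <- apply(dc$X, 2L, sd)
  Xs <- sweep(sweep(dc$X, 2L, object$means), 2L, xsd, "/")
  sc <- cox_schoenfeld_cpp(coef(object) * xsd, dc$entry, dc$exit, dc$status,
                           Xs, object$ties == "efron")
  r <- sweep(sc$residuals, 2L, xsd, "*") # back to original covariate scale
  colnames(r) <- names(coef(object))
  if (type == "scaled_schoenfeld") {
    d <- object$nevent
    r <- d * r %*% object$var + matrix(coef(object), nrow(r),
                                       ncol(r), byrow = TRUE)
    colnames(r) <- names(coef(object))
  }
  attr(r, "time") <- sc$time
  r
}
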