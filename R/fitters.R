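# Outcome adapters: map each estimator's regression recipe onto the three
# supported outcome types so every estimate lands on a collapsible difference
# scale (mean difference, risk difference, hazard difference per year).

# Fast OLS of y on X (X includes the intercept), returning the coefficient and
# model-based (or HC3 robust) SE of the column named `target`.
ols_target <- function(X, y, target, robust = FALSE) {
  f <- lm.fit(X, y)
  if (f$rank < ncol(X)) {
    gmte_abort("singular design: a required regressor is collinear or a stratum is empty",
               "singular")
  }
  k <- match(target, colnames(X))
  beta <- unname(f$coefficients[k])
  if (robust) {
    # sandwich needs a full lm object; refit through the formula interface.
    df <- as.data.frame(X[, -1, drop = FALSE])
    df$.y <- y
    m <- stats::lm(.y ~ ., data = df)
    V <- sandwich::vcovHC(m, type = "HC3")
    se <- sqrt(diag(V))[match(make.names(target), make.names(colnames(X)))]
  } else {
    dfres <- length(y) - f$rank
    if (dfres < 1L) gmte_abort("no residual degrees of freedom", "singular")
    s2 <- sum(f$residuals^2) / dfres
    XtXinv <- chol2inv(qr.R(f$qr))
    se <- sqrt(diag(XtXinv) * s2)[k]
  }
  list(beta = beta, se = unname(se), n = length(y))
}

#' Risk-difference fit for binary outcomes
#'
#' Fits a logistic regression of a binary outcome on the supplied regressors
#' and returns the average marginal effect (AME) of the target regressor on the
#' probability scale, with a delta-method standard error. For a binary target
#' the AME is the average predicted-probability contrast between target = 1 and
#' target = 0; for a continuous target it is the average derivative. With
#' `method = "lpm"` an ordinary linear probability model is used instead (both
#' routes estimate the same collapsible risk difference).
#'
#' @param X numeric model matrix including an intercept column.
#' @param y binary 0/1 outcome vector.
#' @param target name of the column of `X` whose effect is wanted.
#' @param method `"ame"` (logistic + average marginal effect, default) or
#'   `"lpm"` (linear probability model).
#' @param robust use a heteroskedasticity-robust (HC3) SE for the linear
#'   probability model.
#' @return list with `beta`, `se`, `n`.
#' @export
risk_difference_fit <- function(X, y, target, method = c("ame", "lpm"),
                                robust = FALSE) {
  method <- match.arg(method)
  if (!all(y %in% c(0, 1))) gmte_abort("outcome is not binary 0/1", "validation")
  if (method == "lpm") return(ols_target(X, y, target, robust = robust))

  fit <- suppressWarnings(glm.fit(X, y, family = binomial()))
  p_hat <- fit$fitted.values
  if (!fit$converged || any(p_hat < 1e-10) || any(p_hat > 1 - 1e-10)) {
    gmte_abort(paste0("(quasi-)separation in the logistic fit; refit with ",
                      "method = \"lpm\""), "separation")
  }
  beta <- fit$coefficients
  if (anyNA(beta)) gmte_abort("singular design in logistic fit", "singular")
  # vcov = (X' W X)^{-1} from the final IWLS step
  W <- p_hat * (1 - p_hat)
  V <- chol2inv(chol(crossprod(X * sqrt(W))))
  k <- match(target, colnames(X))
  xt <- X[, k]
  binary_target <- all(xt %in% c(0, 1))

  if (binary_target) {
    X1 <- X; X1[, k] <- 1
    X0 <- X; X0[, k] <- 0
    eta1 <- drop(X1 %*% beta); eta0 <- drop(X0 %*% beta)
    ame <- mean(plogis(eta1) - plogis(eta0))
    grad <- colMeans(dlogis(eta1) * X1 - dlogis(eta0) * X0)
  } else {
    eta <- drop(X %*% beta)
    d1 <- dlogis(eta)                      # p(1-p)
    d2 <- d1 * (1 - 2 * plogis(eta))       # derivative of p(1-p) wrt eta
    ame <- beta[k] * mean(d1)
    grad <- beta[k] * colMeans(d2 * X)
    grad[k] <- grad[k] + mean(d1)
  }
  se <- sqrt(drop(t(grad) %*% V %*% grad))
  list(beta = unname(ame), se = se, n = length(y))
}

#' Constant-coefficient additive hazards fit
#'
#' Fits a semiparametric additive hazards model in which each regressor shifts
#' the hazard by a constant amount per unit time (events per person-year),
#' leaving the baseline hazard unspecified. The estimator is the closed-form
#' least-squares solution of the additive-hazards estimating equation with a
#' sandwich (martingale-based) variance. Time-varying coefficient curves are
#' deliberately out of scope: a single hazard difference per regressor is the
#' collapsible analogue of the mean difference used for continuous outcomes.
#'
#' @param time non-negative follow-up times (years).
#' @param event 0/1 event indicators.
#' @param X numeric regressor matrix (no intercept; the baseline hazard plays
#'   that role).
#' @param target name of the column of `X` whose hazard difference is wanted;
#'   if `NULL`, coefficients and SEs for all columns are returned.
#' @return For a single target, list with `beta`, `se`, `n` (per-year scale).
#'   Otherwise a list with vectors `beta`, `se` and the variance matrix `V`.
#' @export
additive_hazards_fit <- function(time, event, X, target = NULL) {
  X <- as.matrix(X)
  n <- length(time)
  stopifnot(nrow(X) == n, length(event) == n)
  if (sum(event) == 0) gmte_abort("no events observed", "no_events")

  ord <- order(time)
  tt <- time[ord]; ev <- event[ord]; Xo <- X[ord, , drop = FALSE]
  p <- ncol(Xo)
  first <- match(tt, tt)              # first index of each tie group
  S0 <- (n:1)                         # suffix risk-set sizes
  suffix <- function(v) rev(cumsum(rev(v)))
  S1 <- apply(Xo, 2, suffix)          # n x p suffix sums
  if (p == 1L) S1 <- matrix(S1, ncol = 1L)

  # A = integral of the risk-set covariance of X; piecewise constant between
  # distinct exit times.
  u <- which(!duplicated(tt))
  dt <- diff(c(0, tt[u]))
  A <- matrix(0, p, p)
  S2u <- array(0, c(length(u), p, p))
  for (j in seq_len(p)) {
    for (k in j:p) {
      s <- suffix(Xo[, j] * Xo[, k])[u]
      S2u[, j, k] <- s
      S2u[, k, j] <- s
    }
  }
  S0u <- S0[u]; S1u <- S1[u, , drop = FALSE]
  for (m in seq_along(u)) {
    if (dt[m] <= 0) next
    A <- A + dt[m] * (S2u[m, , ] - tcrossprod(S1u[m, ]) / S0u[m])
  }

  # Score b and meat B accumulate centred covariates at event times.
  ei <- which(ev == 1)
  xc <- Xo[ei, , drop = FALSE] - S1[first[ei], , drop = FALSE] / S0[first[ei]]
  b <- colSums(xc)
  B <- crossprod(xc)

  Ainv <- tryCatch(solve(A), error = function(e) {
    gmte_abort("singular design in additive hazards fit (empty stratum?)",
               "singular")
  })
  beta <- drop(Ainv %*% b)
  V <- Ainv %*% B %*% t(Ainv)
  se <- sqrt(diag(V))
  names(beta) <- names(se) <- colnames(X)

  if (is.null(target)) return(list(beta = beta, se = se, V = V, n = n))
  k <- match(target, colnames(X))
  list(beta = unname(beta[k]), se = unname(se[k]), n = n)
}

# Unified dispatcher used by all estimators: regress the outcome of `data` on
# the named derived/design columns (plus covariates, always additive), and
# return beta/se/n for `target` on the outcome-appropriate difference scale.
fit_target <- function(data, terms, target, robust = FALSE,
                       binary_method = c("ame", "lpm")) {
  stopifnot(inherits(data, "pg_data"))
  binary_method <- match.arg(binary_method)
  d <- data$data
  cols <- c(terms, data$covariates)
  M <- as.matrix(d[cols])
  storage.mode(M) <- "double"

  if (data$outcome_type == "survival") {
    # required-stratum event check for binary target regressors
    xt <- d[[target]]
    if (all(xt %in% c(0, 1)) && length(unique(xt)) == 2L) {
      ev_by <- tapply(d$event, xt, sum)
      if (any(ev_by == 0)) {
        gmte_abort("zero events in a required stratum", "no_events")
      }
    }
    return(additive_hazards_fit(d$time, d$event, M, target = target))
  }

  X <- cbind(`(Intercept)` = 1, M)
  if (data$outcome_type == "binary") {
    return(risk_difference_fit(X, d$Y, target, method = binary_method,
                               robust = robust))
  }
  ols_target(X, d$Y, target, robust = robust)
}

# Effect scale implied by the outcome type.
outcome_scale <- function(outcome_type) {
  switch(outcome_type,
         continuous = "mean_difference",
         binary = "risk_difference",
         survival = "hazard_difference")
}
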