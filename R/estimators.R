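# The five estimators of the genetically moderated treatment effect (GMTE).
# All are reported on the collapsible difference scale implied by the outcome
# type; the sufficient identifying assumptions attached to each estimate use
# the shorthand:
#   PG1: genotype independent of treatment given unmeasured confounders
#   PG2: genotype independent of confounders
#   PG3: genotype independent of outcome given treatment and confounders
#   NUC: no unmeasured confounding of treatment and outcome
#   Hom: no treatment effect in the reference-genotype group

new_gmte_estimate <- function(label, fit, assumptions, data, percent = FALSE) {
  se <- fit$se
  if (!is.finite(se) || se < 0) {
    gmte_abort(paste0(label, ": standard error is not finite (degenerate fit)"),
               "singular")
  }
  if (se == 0) {
    gmte_warn(paste0(label, ": zero residual variation; SE is degenerate"),
              "degenerate")
  }
  structure(
    list(label = label, beta = fit$beta, se = se,
         p = if (se > 0) 2 * pnorm(-abs(fit$beta / se)) else NA_real_,
         n = fit$n,
         assumptions = assumptions,
         scale = outcome_scale(data$outcome_type), percent = percent),
    class = "gmte_estimate"
  )
}

#' @export
print.gmte_estimate <- function(x, ...) {
  unit <- switch(x$scale,
                 mean_difference = "mean difference",
                 risk_difference = "risk difference",
                 hazard_difference = if (x$percent)
                   "% hazard difference / year" else "hazard difference / year")
  cat(sprintf("%s estimate: %.4g (SE %.3g, p = %.3g, n = %d) [%s]\n",
              x$label, x$beta, x$se, x$p, x$n, unit))
  cat("Sufficient assumptions: ", x$assumptions, "\n", sep = "")
  invisible(x)
}

#' Rescale a hazard-difference estimate to the percent-per-year scale
#'
#' Display transform only: multiplies the point estimate and SE by 100 and
#' flags the estimate, leaving the p-value untouched.
#'
#' @param x a `gmte_estimate` on the per-year hazard-difference scale.
#' @return The estimate on the percent scale.
#' @export
as_percent <- function(x) {
  stopifnot(inherits(x, "gmte_estimate"))
  if (x$scale != "hazard_difference" || x$percent) return(x)
  x$beta <- 100 * x$beta
  x$se <- 100 * x$se
  x$percent <- TRUE
  x
}

check_cells <- function(d, rows, label, min_per_cell = 2L) {
  counts <- table(factor(d$G[rows], levels = 0:1))
  if (any(counts < min_per_cell)) {
    gmte_abort(paste0(label, ": a genotype level has fewer than ",
                      min_per_cell, " rows in the required stratum"),
               "singular")
  }
}

#' Treated-population genotype contrast (GMTE(1))
#'
#' The coefficient of `T_star` in the additive model of the outcome on `T`,
#' `T_star` and the covariates: the genotype contrast among the treated. This
#' is the workhorse pharmacogenetic estimate; it is consistent for the GMTE
#' when PG3 holds together with either (PG1 and PG2) or NUC. For a
#' treated-only dataset the recipe reduces to regressing the outcome on `G`
#' plus covariates.
#'
#' @param data a [pg_data()] object.
#' @param alpha two-sided significance level carried along for downstream
#'   gating (default 0.05).
#' @param robust use heteroskedasticity-robust SEs (continuous/linear
#'   probability fits only).
#' @param binary_method risk-difference route for binary outcomes: logistic
#'   average marginal effect (`"ame"`, default) or linear probability model
#'   (`"lpm"`).
#' @return A `gmte_estimate`.
#' @export
gmte1 <- function(data, alpha = 0.05, robust = FALSE,
                  binary_method = c("ame", "lpm")) {
  stopifnot(inherits(data, "pg_data"))
  d <- data$data
  check_cells(d, d$T == 1, "gmte1")
  terms <- if (data$treated_only) "T_star" else c("T", "T_star")
  fit <- fit_target(data, terms, "T_star", robust = robust,
                    binary_method = match.arg(binary_method))
  new_gmte_estimate("GMTE1", fit, "PG3 & {(PG1 & PG2) | NUC}", data)
}

#' Untreated-population genotype contrast (GMTE(0))
#'
#' The coefficient of `T_star_minus` in the additive model of the outcome on
#' `T_minus`, `T_star_minus` and covariates: the genotype contrast among the
#' untreated. Under the pharmacogenetic assumptions this targets zero, so it
#' is a falsification (bias) estimate rather than an estimate of the GMTE
#' itself.
#'
#' @inheritParams gmte1
#' @return A `gmte_estimate` (target value 0 under PG assumptions).
#' @export
gmte0 <- function(data, alpha = 0.05, robust = FALSE,
                  binary_method = c("ame", "lpm")) {
  stopifnot(inherits(data, "pg_data"))
  if (data$treated_only) {
    gmte_abort("gmte0 requires untreated rows", "singular")
  }
  d <- data$data
  check_cells(d, d$T == 0, "gmte0")
  fit <- fit_target(data, c("T_minus", "T_star_minus"), "T_star_minus",
                    robust = robust, binary_method = match.arg(binary_method))
  new_gmte_estimate("GMTE0", fit, "PG3 & {(PG1 & PG2) | NUC}", data)
}

#' Robust GMTE estimate
#'
#' Subtracts the untreated genotype contrast from the treated one, removing
#' bias channels that act identically in both treatment groups (direct
#' genotype-outcome effects, genotype-confounder leaks). Consistent whenever
#' PG1 or NUC holds. Two numerically near-identical fitting routes are
#' provided: `"regression"` (default) takes the coefficient of `T_star` in the
#' joint model with `T`, `T_star`, `T_hat_star` and covariates; `"difference"`
#' literally computes `gmte1 - gmte0` with the two SEs added in quadrature
#' (the treated and untreated contrasts use disjoint outcome information).
#' Without covariates the two routes coincide to machine precision; with
#' covariates the joint model pools the covariate slopes across treatment
#' groups and the routes differ at order 1/n.
#'
#' @inheritParams gmte1
#' @param method `"regression"` or `"difference"`.
#' @return A `gmte_estimate`.
#' @export
rgmte <- function(data, alpha = 0.05, method = c("regression", "difference"),
                  robust = FALSE, binary_method = c("ame", "lpm")) {
  stopifnot(inherits(data, "pg_data"))
  method <- match.arg(method)
  binary_method <- match.arg(binary_method)
  if (data$treated_only) {
    gmte_abort("rgmte requires both treatment groups", "singular")
  }
  d <- data$data
  check_cells(d, d$T == 1, "rgmte")
  check_cells(d, d$T == 0, "rgmte")
  if (method == "difference") {
    e1 <- gmte1(data, alpha, robust, binary_method)
    e0 <- gmte0(data, alpha, robust, binary_method)
    fit <- list(beta = e1$beta - e0$beta,
                se = sqrt(e1$se^2 + e0$se^2), n = nrow(d))
  } else {
    fit <- fit_target(data, c("T", "T_star", "T_hat_star"), "T_star",
                      robust = robust, binary_method = binary_method)
  }
  new_gmte_estimate("RGMTE", fit, "PG1 | NUC", data)
}

#' Mendelian-randomization estimate of the GMTE
#'
#' Uses the genotype as an instrument for the treatment-moderator `T_star`:
#' the Wald ratio of the genotype-outcome and genotype-moderator associations,
#' implemented as the coefficient of the genotype-predicted moderator
#' `T_hat_star` in a model with covariates. The second-stage SE is reported
#' as-is (first-stage uncertainty is ignored, which is anti-conservative in
#' small samples). Because `T_star = T * G` forces `E[T_star | G = 0] = 0`,
#' the instrument denominator equals the treated fraction among carriers; a
#' warning is raised when fewer than 10 treated carriers support it.
#'
#' @inheritParams gmte1
#' @return A `gmte_estimate`.
#' @export
gmte_mr <- function(data, alpha = 0.05, robust = FALSE,
                    binary_method = c("ame", "lpm")) {
  stopifnot(inherits(data, "pg_data"))
  d <- data$data
  if (length(unique(d$G)) < 2L) {
    gmte_abort("genotype is constant: no instrument contrast", "weak_instrument")
  }
  if (data$treated_only) {
    gmte_abort("gmte_mr requires both treatment groups", "singular")
  }
  denom <- mean(d$T_star[d$G == 1]) - mean(d$T_star[d$G == 0])
  if (abs(denom) < 1e-10) {
    gmte_abort("instrument denominator E[T*|G=1] - E[T*|G=0] is (numerically) zero",
               "weak_instrument")
  }
  if (sum(d$T_star) < 10) {
    gmte_warn(paste0("only ", sum(d$T_star), " treated carriers support the ",
                     "instrument; the MR estimate may be severely imprecise"),
              "weak_instrument")
  }
  fit <- fit_target(data, "T_hat_star", "T_hat_star", robust = robust,
                    binary_method = match.arg(binary_method))
  new_gmte_estimate("MR", fit, "{PG1 | Hom} & {PG2 | NUC} & PG3", data)
}

#' Corrected as-treated estimate of the GMTE
#'
#' Rescales the covariate-adjusted treated-vs-untreated outcome difference by
#' the carrier proportion among the treated, implemented as the coefficient of
#' `T_cat = mean(G | T = 1) * T` in a model with covariates. Valid only when
#' confounding by indication is fully captured by the covariates (NUC), the
#' reference genotype receives no treatment effect (Hom), and PG1 or PG3
#' holds.
#'
#' @inheritParams gmte1
#' @return A `gmte_estimate`.
#' @export
gmte_cat <- function(data, alpha = 0.05, robust = FALSE,
                     binary_method = c("ame", "lpm")) {
  stopifnot(inherits(data, "pg_data"))
  d <- data$data
  if (data$treated_only) {
    gmte_abort("the corrected as-treated estimate requires untreated rows",
               "singular")
  }
  if (is.null(d$T_cat) || mean(d$G[d$T == 1]) == 0) {
    gmte_abort("no carriers among the treated: correction factor undefined",
               "singular")
  }
  if (sum(d$T == 1) < 2L || sum(d$T == 0) < 2L) {
    gmte_abort("gmte_cat: a treatment stratum has fewer than 2 rows", "singular")
  }
  fit <- fit_target(data, "T_cat", "T_cat", robust = robust,
                    binary_method = match.arg(binary_method))
  new_gmte_estimate("CAT", fit, "{PG1 | PG3} & NUC & Hom", data)
}

#' Fit all five GMTE estimators
#'
#' Convenience wrapper returning the five single estimates in the canonical
#' order CAT, GMTE0, GMTE1, MR, RGMTE. Estimators that fail on the supplied
#' dataset (e.g. everything but `gmte1` on a treated-only dataset) are
#' returned as `NULL` with a message, not an error.
#'
#' @inheritParams gmte1
#' @param rgmte_method passed to [rgmte()].
#' @return Named list of `gmte_estimate` objects (entries `NULL` when
#'   unavailable).
#' @export
fit_gmte <- function(data, alpha = 0.05, robust = FALSE,
                     binary_method = c("ame", "lpm"),
                     rgmte_method = c("regression", "difference")) {
  binary_method <- match.arg(binary_method)
  rgmte_method <- match.arg(rgmte_method)
  fits <- list(
    CAT = function() gmte_cat(data, alpha, robust, binary_method),
    GMTE0 = function() gmte0(data, alpha, robust, binary_method),
    GMTE1 = function() gmte1(data, alpha, robust, binary_method),
    MR = function() gmte_mr(data, alpha, robust, binary_method),
    RGMTE = function() rgmte(data, alpha, rgmte_method, robust, binary_method)
  )
  lapply(fits, function(f) {
    tryCatch(f(), gmte_error = function(e) {
      message("estimator unavailable: ", conditionMessage(e))
      NULL
    })
  })
}
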