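# Estimator-specific confounder diagnostics: re-run an estimator's recipe
# with a candidate confounder in place of the outcome. A non-zero result
# flags a bias channel for that estimator unless the variable is adjusted
# for. Binary candidates are handled on the linear-probability scale.

#' Confounder test for a GMTE estimator
#'
#' Re-fits the named estimator's continuous-outcome recipe using a measured
#' variable as the outcome. Under the estimator's identifying assumptions the
#' result targets zero, so a small p-value signals a potential bias channel:
#' the variable predicts the contrast the estimator relies on and should be
#' adjusted for. The tested variable is always removed from the adjustment
#' set of its own test. For the corrected as-treated estimator the genotype
#' itself may be tested (`variable = "G"`), probing carrier-frequency
#' imbalance between treatment groups.
#'
#' @param data a [pg_data()] object.
#' @param estimator one of `"CAT"`, `"GMTE0"`, `"GMTE1"`, `"RGMTE"`, `"MR"`.
#' @param variable name of a covariate column of `data` (or `"G"` for the CAT
#'   test).
#' @param alpha verdict threshold (default 0.05).
#' @return A `gmte_confounder_test`: list with `estimator`, `variable`,
#'   `beta`, `se`, `p`, `flagged` (TRUE when `p < alpha`).
#' @export
confounder_test <- function(data, estimator, variable, alpha = 0.05) {
  stopifnot(inherits(data, "pg_data"))
  estimator <- match.arg(estimator, c("CAT", "GMTE0", "GMTE1", "RGMTE", "MR"))
  if (identical(variable, "G") && estimator != "CAT") {
    gmte_abort("the genotype can only be the test outcome for the CAT estimator",
               "validation")
  }
  if (!identical(variable, "G") && !variable %in% data$covariates) {
    gmte_abort(paste0("'", variable, "' is not a covariate of the dataset"),
               "validation")
  }
  v <- data$data[[variable]]
  if (length(unique(v)) < 2L) {
    gmte_abort(paste0("'", variable, "' is constant: test undefined"),
               "constant")
  }

  # Swap the candidate in as a continuous outcome; drop it from adjustment.
  test_data <- data
  test_data$outcome_type <- "continuous"
  test_data$data$Y <- as.numeric(v)
  test_data$covariates <- setdiff(data$covariates, variable)

  est <- switch(estimator,
                CAT = gmte_cat(test_data, alpha),
                GMTE0 = gmte0(test_data, alpha),
                GMTE1 = gmte1(test_data, alpha),
                RGMTE = rgmte(test_data, alpha),
                MR = gmte_mr(test_data, alpha))
  structure(
    list(estimator = estimator, variable = variable, beta = est$beta,
         se = est$se, p = est$p, alpha = alpha, flagged = est$p < alpha),
    class = "gmte_confounder_test"
  )
}

#' @export
print.gmte_confounder_test <- function(x, ...) {
  cat(sprintf("%s confounder test for '%s': beta = %.4g (SE %.3g, p = %.3g)\n",
              x$estimator, x$variable, x$beta, x$se, x$p))
  cat(if (x$flagged) {
    "Potential bias: adjust for this variable.\n"
  } else {
    "No evidence of bias through this variable.\n"
  })
  invisible(x)
}

#' Grid of confounder tests
#'
#' Runs [confounder_test()] for every combination of the requested estimators
#' and variables, optionally applying a Bonferroni correction across the
#' tested variables (none by default).
#'
#' @inheritParams confounder_test
#' @param estimators character vector of estimator labels.
#' @param variables character vector of covariate names (defaults to all
#'   covariates of `data`).
#' @param bonferroni correct the verdict threshold for the number of
#'   variables tested.
#' @return Data frame with one row per (estimator, variable) pair.
#' @export
confounder_scan <- function(data, estimators = c("CAT", "GMTE0", "GMTE1",
                                                 "RGMTE", "MR"),
                            variables = data$covariates, alpha = 0.05,
                            bonferroni = FALSE) {
  thr <- if (bonferroni) alpha / length(variables) else alpha
  grid <- expand.grid(estimator = estimators, variable = variables,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    ct <- confounder_test(data, grid$estimator[i], grid$variable[i],
                          alpha = thr)
    data.frame(estimator = ct$estimator, variable = ct$variable,
               beta = ct$beta, se = ct$se, p = ct$p, flagged = ct$flagged)
  })
  do.call(rbind, res)
}
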