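# Inverse-variance-weighted pooling of approximately uncorrelated estimates,
# gated by a Cochran-type heterogeneity statistic.

#' Inverse-variance-weighted combination of 2-3 estimates
#'
#' Pools component estimates with weights `1/se^2`, and computes the
#' heterogeneity statistic `Q = sum(w * (beta - pooled)^2)` which is referred
#' to a chi-square distribution with `k - 1` degrees of freedom. The `pass`
#' flag records whether the components are homogeneous enough to combine
#' (`Q` p-value at or above `alpha`); failing combinations are still returned
#' with their statistics so they can be reported rather than silently
#' discarded.
#'
#' Components must share a scale: estimates carried as `gmte_estimate` objects
#' are checked for matching outcome scale and percent flag, and mixing raises
#' a coded error.
#'
#' @param components either a list of `gmte_estimate` objects or a data frame
#'   with columns `label`, `beta`, `se` (summary-level use, e.g. reproducing a
#'   published results table).
#' @param alpha significance level of the heterogeneity gate (default 0.05).
#' @return A `gmte_combined` object: list with `labels`, `beta`, `se`, `p`,
#'   `Q`, `Q_df`, `Q_p`, `pass`, `alpha`, `scale`, `percent`.
#' @export
#' @examples
#' ivw_combine(data.frame(label = c("RGMTE", "MR"),
#'                        beta = c(0.33, 0.29), se = c(0.16, 0.11)))
ivw_combine <- function(components, alpha = 0.05) {
  if (!(is.numeric(alpha) && length(alpha) == 1L && alpha > 0 && alpha < 1)) {
    gmte_abort("alpha must be a single value in (0, 1)", "validation")
  }
  scale <- NA_character_
  percent <- NA
  if (is.data.frame(components)) {
    labels <- as.character(components$label)
    beta <- as.numeric(components$beta)
    se <- as.numeric(components$se)
  } else if (is.list(components) &&
             all(vapply(components, inherits, TRUE, "gmte_estimate"))) {
    labels <- vapply(components, `[[`, "", "label")
    beta <- vapply(components, `[[`, 0, "beta")
    se <- vapply(components, `[[`, 0, "se")
    scales <- vapply(components, `[[`, "", "scale")
    percents <- vapply(components, `[[`, TRUE, "percent")
    if (length(unique(scales)) > 1L || length(unique(percents)) > 1L) {
      gmte_abort("components are on different effect scales", "scale")
    }
    scale <- scales[1]
    percent <- percents[1]
  } else {
    gmte_abort("components must be gmte_estimate objects or a label/beta/se data frame",
               "validation")
  }
  k <- length(beta)
  if (!k %in% 2:3) {
    gmte_abort("only 2- or 3-way combinations are supported", "combine")
  }
  if (any(!is.finite(se)) || any(se <= 0)) {
    gmte_abort("all component standard errors must be positive", "validation")
  }

  w <- 1 / se^2
  pooled <- sum(w * beta) / sum(w)
  pooled_se <- 1 / sqrt(sum(w))
  Q <- sum(w * (beta - pooled)^2)
  Q_df <- k - 1L
  Q_p <- pchisq(Q, df = Q_df, lower.tail = FALSE)
  structure(
    list(labels = labels, beta = pooled, se = pooled_se,
         p = 2 * pnorm(-abs(pooled / pooled_se)),
         Q = Q, Q_df = Q_df, Q_p = Q_p, pass = Q_p >= alpha, alpha = alpha,
         scale = scale, percent = percent),
    class = "gmte_combined"
  )
}

#' @export
print.gmte_combined <- function(x, ...) {
  cat(sprintf("%s combined estimate: %.4g (SE %.3g, p = %.3g)\n",
              paste(x$labels, collapse = "/"), x$beta, x$se, x$p))
  cat(sprintf("Heterogeneity: Q = %.3g on %d df, p = %.3g -> %s (alpha = %g)\n",
              x$Q, x$Q_df, x$Q_p,
              if (x$pass) "combine" else "do not combine", x$alpha))
  invisible(x)
}

# The five sanctioned combinations. RGMTE and MR are each highly correlated
# with GMTE1, so GMTE1 is only ever paired with CAT.
sanctioned_combinations <- list(
  c("CAT", "GMTE1"),
  c("CAT", "RGMTE"),
  c("CAT", "MR"),
  c("RGMTE", "MR"),
  c("CAT", "RGMTE", "MR")
)

#' Enumerate the nine single and combined GMTE estimates
#'
#' From the four single estimates (CAT, GMTE1, RGMTE, MR) forms the five
#' sanctioned approximately-uncorrelated combinations -- CAT/GMTE1, CAT/RGMTE,
#' CAT/MR, RGMTE/MR and CAT/RGMTE/MR -- and returns all nine results with
#' heterogeneity statistics and pass flags. Pairs involving GMTE1 with RGMTE
#' or MR are never formed (those estimates are strongly correlated, so their
#' agreement carries no evidential weight). A missing single estimate renders
#' it and every combination containing it explicitly unavailable in the
#' output rather than silently absent.
#'
#' @param estimates named list with entries `CAT`, `GMTE1`, `RGMTE`, `MR`
#'   (each a `gmte_estimate` or `NULL`), e.g. from [fit_gmte()]; or a data
#'   frame with columns `label`, `beta`, `se` containing those four labels
#'   (summary-level use).
#' @param alpha heterogeneity-gate significance level.
#' @return A `gmte_triangulation` object; its `table` element is a data frame
#'   with one row per result (`label`, `kind`, `beta`, `se`, `p`, `Q`, `Q_df`,
#'   `Q_p`, `pass`, `available`).
#' @export
triangulate <- function(estimates, alpha = 0.05) {
  if (is.data.frame(estimates)) {
    need <- c("CAT", "GMTE1", "RGMTE", "MR")
    estimates <- setNames(lapply(need, function(l) {
      i <- which(estimates$label == l)
      if (!length(i)) return(NULL)
      structure(list(label = l, beta = estimates$beta[i[1]],
                     se = estimates$se[i[1]],
                     p = 2 * pnorm(-abs(estimates$beta[i[1]] / estimates$se[i[1]])),
                     n = NA_integer_, assumptions = "",
                     scale = "summary", percent = NA),
                class = "gmte_estimate")
    }), need)
  }
  singles <- c("CAT", "GMTE1", "RGMTE", "MR")
  rows <- list()
  for (l in singles) {
    e <- estimates[[l]]
    rows[[l]] <- if (is.null(e)) {
      data.frame(label = l, kind = "single", beta = NA_real_, se = NA_real_,
                 p = NA_real_, Q = NA_real_, Q_df = NA_integer_,
                 Q_p = NA_real_, pass = NA, available = FALSE)
    } else {
      data.frame(label = l, kind = "single", beta = e$beta, se = e$se,
                 p = e$p, Q = NA_real_, Q_df = NA_integer_, Q_p = NA_real_,
                 pass = NA, available = TRUE)
    }
  }
  combos <- list()
  for (cc in sanctioned_combinations) {
    lab <- paste(cc, collapse = "/")
    parts <- estimates[cc]
    if (any(vapply(parts, is.null, TRUE))) {
      combos[[lab]] <- data.frame(label = lab, kind = "combined",
                                  beta = NA_real_, se = NA_real_, p = NA_real_,
                                  Q = NA_real_, Q_df = NA_integer_,
                                  Q_p = NA_real_, pass = NA, available = FALSE)
      next
    }
    cmb <- ivw_combine(parts, alpha = alpha)
    combos[[lab]] <- data.frame(label = lab, kind = "combined",
                                beta = cmb$beta, se = cmb$se, p = cmb$p,
                                Q = cmb$Q, Q_df = cmb$Q_df, Q_p = cmb$Q_p,
                                pass = cmb$pass, available = TRUE)
  }
  tab <- do.call(rbind, c(rows, combos))
  rownames(tab) <- NULL
  structure(list(table = tab, alpha = alpha, estimates = estimates),
            class = "gmte_triangulation")
}

#' @export
print.gmte_triangulation <- function(x, digits = 4, ...) {
  cat("Triangulation of GMTE estimates (alpha = ", x$alpha, ")\n\n", sep = "")
  tab <- x$table
  tab$beta <- signif(tab$beta, digits)
  tab$se <- signif(tab$se, digits)
  tab$p <- signif(tab$p, 3)
  tab$Q <- signif(tab$Q, 3)
  tab$Q_p <- signif(tab$Q_p, 3)
  tab$combine <- ifelse(is.na(tab$pass), "",
                        ifelse(tab$pass, "yes", "no"))
  print(tab[c("label", "kind", "beta", "se", "p", "Q", "Q_p", "combine")],
        row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.gmte_triangulation <- function(x, ...) x$table
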