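# Reporting utilities: avoided-event translation, forest plots with
# heterogeneity pass/fail colour coding, and an end-to-end pipeline wrapper.

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Translate a per-year hazard difference into avoided events
#'
#' Multiplies a hazard difference expressed in percent per year by the
#' person-years of observation to give the expected number of events that
#' would be added or avoided, with a 95% interval. Rounding to whole events is
#' half-away-from-zero and happens only at the final step.
#'
#' @param beta_percent hazard difference in percent per year (e.g. `0.33`
#'   for 0.33% per year).
#' @param se standard error on the same percent scale (may be `NA` if only
#'   the point count is wanted).
#' @param person_years person-years the difference acts over; must be
#'   positive.
#' @return An `avoided_events` object: list with `count` (signed), `lower`,
#'   `upper` (95% interval, same sign convention), `magnitude`
#'   (`abs(count)`), and the inputs.
#' @export
#' @examples
#' avoided_events(0.33, 0.16, 5264)  # 17 events
avoided_events <- function(beta_percent, se = NA_real_, person_years) {
  if (!(is.numeric(person_years) && person_years > 0)) {
    gmte_abort("person_years must be positive", "validation")
  }
  if (!is.na(se) && se < 0) gmte_abort("se must be non-negative", "validation")
  count <- round_half_away(beta_percent / 100 * person_years)
  if (is.na(se)) {
    lower <- upper <- NA_real_
  } else {
    lo <- (beta_percent - 1.96 * se) / 100 * person_years
    hi <- (beta_percent + 1.96 * se) / 100 * person_years
    lower <- round_half_away(lo)
    upper <- round_half_away(hi)
  }
  structure(
    list(count = count, lower = lower, upper = upper,
         magnitude = abs(count), beta_percent = beta_percent, se = se,
         person_years = person_years),
    class = "avoided_events"
  )
}

#' @export
print.avoided_events <- function(x, ...) {
  dir <- if (x$beta_percent >= 0) "avoided" else "added"
  ci <- if (is.na(x$lower)) "" else sprintf(" (95%% CI %g to %g)", x$lower, x$upper)
  cat(sprintf("%g events %s over %g person-years%s\n",
              x$magnitude, dir, x$person_years, ci))
  cat(sprintf("  (hazard difference %g%% per year)\n", x$beta_percent))
  invisible(x)
}

#' Forest plot of a triangulation
#'
#' Renders the nine single/combined estimates (and optionally the GMTE0
#' falsification estimate) with point estimates and 95% whiskers. Single
#' estimates and combinations passing the heterogeneity gate share one colour
#' class; failing combinations a second; the falsification estimate is
#' visually distinct. Layout is deterministic: rows follow the triangulation
#' table order.
#'
#' @param tri a `gmte_triangulation` (from [triangulate()]) or its table.
#' @param gmte0 optional `gmte_estimate` for the untreated-group
#'   falsification contrast.
#' @param file optional output path (`.png`, `.svg`, `.pdf`); when `NULL` the
#'   ggplot object is returned without writing.
#' @param width,height device size in inches when writing.
#' @return The ggplot object, invisibly when written to file.
#' @export
forest_plot <- function(tri, gmte0 = NULL, file = NULL, width = 7,
                        height = 4.5) {
  tab <- if (inherits(tri, "gmte_triangulation")) tri$table else tri
  tab <- tab[tab$available %in% c(TRUE, NA), , drop = FALSE]
  if (!nrow(tab)) gmte_abort("nothing to plot", "validation")
  tab$class <- ifelse(tab$kind == "single" | tab$pass %in% TRUE,
                      "estimate / combined (pass)", "combined (fail)")
  if (!is.null(gmte0)) {
    tab <- rbind(tab[, c("label", "beta", "se", "class")],
                 data.frame(label = "GMTE0 (falsification)",
                            beta = gmte0$beta, se = gmte0$se,
                            class = "falsification"))
  } else {
    tab <- tab[, c("label", "beta", "se", "class")]
  }
  tab$label <- factor(tab$label, levels = rev(tab$label))
  pal <- c("estimate / combined (pass)" = "#2166ac",
           "combined (fail)" = "#1a1a1a",
           "falsification" = "#b2182b")
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$beta, y = .data$label,
                                         colour = .data$class)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$beta - 1.96 * .data$se,
                                         xmax = .data$beta + 1.96 * .data$se),
                            height = 0.2) +
    ggplot2::geom_point(shape = 15, size = 2.5) +
    ggplot2::scale_colour_manual(values = pal, name = NULL) +
    ggplot2::labs(x = "GMTE estimate (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = width, height = height)
    return(invisible(p))
  }
  p
}

#' End-to-end GMTE analysis
#'
#' Runs the full workflow on an individual-level dataset: fit the five single
#' estimators, enumerate the nine single/combined estimates with the
#' heterogeneity gate, and scan the covariates with every estimator's
#' confounder test. Each model fit is logged with its row count via
#' `message()`.
#'
#' @param data a [pg_data()] object, or a file path to delimited text (then
#'   the column-mapping arguments of [read_pg_data()] apply).
#' @param alpha significance level for gating and verdicts.
#' @param diagnostics run the confounder scan (default TRUE when covariates
#'   are present).
#' @param plot_file optional path for a forest plot of the results.
#' @param ... passed to [read_pg_data()] when `data` is a path.
#' @return A `gmte_bundle`: list with `estimates` (data frame of the five
#'   singles), `triangulation` (the nine-row table), `diagnostics` (data
#'   frame or `NULL`), `meta` (JSON string).
#' @export
gmte_pipeline <- function(data, alpha = 0.05, diagnostics = NULL,
                          plot_file = NULL, ...) {
  if (is.character(data)) data <- read_pg_data(data, ...)
  stopifnot(inherits(data, "pg_data"))
  message("dataset: ", pg_data_meta(data))

  fits <- fit_gmte(data, alpha = alpha)
  for (f in fits) {
    if (!is.null(f)) {
      message(f$label, " fitted on ", f$n, " rows: beta = ",
              signif(f$beta, 4), " (se ", signif(f$se, 3), ")")
    }
  }
  tri <- triangulate(fits[c("CAT", "GMTE1", "RGMTE", "MR")], alpha = alpha)

  if (is.null(diagnostics)) diagnostics <- length(data$covariates) > 0
  diag_tab <- NULL
  if (isTRUE(diagnostics) && length(data$covariates)) {
    avail <- names(Filter(Negate(is.null), fits))
    diag_tab <- confounder_scan(data, estimators = avail, alpha = alpha)
  }

  if (!is.null(plot_file)) {
    forest_plot(tri, gmte0 = fits$GMTE0, file = plot_file)
  }

  est_tab <- do.call(rbind, lapply(Filter(Negate(is.null), fits), function(e)
    data.frame(label = e$label, beta = e$beta, se = e$se, p = e$p, n = e$n,
               assumptions = e$assumptions, scale = e$scale)))
  rownames(est_tab) <- NULL
  structure(
    list(estimates = est_tab, triangulation = tri$table,
         diagnostics = diag_tab, meta = pg_data_meta(data), alpha = alpha),
    class = "gmte_bundle"
  )
}

#' @export
print.gmte_bundle <- function(x, ...) {
  cat("GMTE analysis bundle\n====================\n\nSingle estimates:\n")
  est <- x$estimates
  est$beta <- signif(est$beta, 4); est$se <- signif(est$se, 3)
  est$p <- signif(est$p, 3)
  print(est[c("label", "beta", "se", "p", "n")], row.names = FALSE)
  cat("\nTriangulation:\n")
  tab <- x$triangulation
  tab$beta <- signif(tab$beta, 4); tab$se <- signif(tab$se, 3)
  tab$p <- signif(tab$p, 3); tab$Q <- signif(tab$Q, 3)
  tab$Q_p <- signif(tab$Q_p, 3)
  print(tab[c("label", "beta", "se", "p", "Q", "Q_p", "pass")],
        row.names = FALSE)
  if (!is.null(x$diagnostics)) {
    flagged <- x$diagnostics[x$diagnostics$flagged, , drop = FALSE]
    cat("\nConfounder tests flagged:", nrow(flagged), "of",
        nrow(x$diagnostics), "\n")
  }
  invisible(x)
}

#' Write an analysis bundle to disk
#'
#' Serialises the bundle as a JSON file plus CSVs of the estimate and
#' triangulation tables. Re-running on identical inputs produces identical
#' files.
#'
#' @param bundle a `gmte_bundle` from [gmte_pipeline()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "gmte_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    json = file.path(dir, "bundle.json"),
    estimates = file.path(dir, "estimates.csv"),
    triangulation = file.path(dir, "triangulation.csv")
  )
  jsonlite::write_json(
    list(estimates = bundle$estimates, triangulation = bundle$triangulation,
         diagnostics = bundle$diagnostics,
         meta = jsonlite::fromJSON(bundle$meta), alpha = bundle$alpha),
    paths["json"], auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.csv(bundle$estimates, paths["estimates"], row.names = FALSE)
  utils::write.csv(bundle$triangulation, paths["triangulation"],
                   row.names = FALSE)
  invisible(paths)
}
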