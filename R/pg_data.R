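#' Construct a pharmacogenetic analysis dataset
#'
#' Bundles a binary genotype indicator `G` (1 = the treatment-enabling or
#' variant-carrier group, 0 = reference), a binary treatment indicator `T`, an
#' outcome, and optional measured covariates into a validated object carrying
#' the derived regressors used by every estimator:
#'
#' * `T_star = T * G`, the treatment-moderator regressor;
#' * `T_minus = 1 - T` and `T_star_minus = (1 - T) * G`, its untreated-group
#'   counterparts;
#' * `T_hat_star`, the within-genotype-level sample mean of `T_star`
#'   (the genotype-predicted moderator, i.e. the first stage of the
#'   instrumental-variable estimator);
#' * `T_cat`, `T` rescaled by the carrier proportion among the treated,
#'   `mean(G | T = 1) * T` (present only when at least one row is treated).
#'
#' Genotype coding is the caller's responsibility: the package never infers
#' which allele group is treatment-enabling from the data.
#'
#' @param df data frame holding at least the genotype and treatment columns.
#' @param g,t names of the genotype and treatment columns.
#' @param y name of the outcome column (continuous or binary outcomes).
#' @param time,event names of the follow-up time (years) and event indicator
#'   columns (survival outcomes).
#' @param covariates character vector of covariate column names; these are
#'   carried along and included additively in every fitted model.
#' @param outcome_type one of `"continuous"`, `"binary"`, `"survival"`.
#'
#' @return An object of class `pg_data`: a list with elements `data` (the
#'   validated data frame including derived columns), `outcome_type`,
#'   `covariates`, and `treated_only` (flag set when every row is treated,
#'   in which case only the treated-population genotype contrast [gmte1()] is
#'   estimable).
#' @seealso [read_pg_data()] to build one directly from a delimited text file.
#' @export
#' @examples
#' d <- data.frame(G = c(0, 1, 0, 1), T = c(1, 1, 0, 0), Y = rnorm(4))
#' pd <- pg_data(d)
#' pd$data$T_star
pg_data <- function(df, g = "G", t = "T", y = "Y", time = "time",
                    event = "event",
                    covariates = character(),
                    outcome_type = c("continuous", "binary", "survival")) {
  outcome_type <- match.arg(outcome_type)
  need <- c(g, t, covariates,
            if (outcome_type == "survival") c(time, event) else y)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    gmte_abort(paste0("mapped column(s) not found: ",
                      paste(missing_cols, collapse = ", ")), "validation")
  }

  keep <- complete.cases(df[need])
  dropped <- sum(!keep)
  if (dropped > 0L) {
    message(dropped, " row(s) dropped: missing values in mapped columns")
    df <- df[keep, , drop = FALSE]
  }
  if (nrow(df) == 0L) {
    gmte_abort("no rows remain after removing incomplete cases", "validation")
  }

  G <- coerce_binary(df[[g]], "genotype")
  Tr <- coerce_binary(df[[t]], "treatment")

  out <- data.frame(G = G, T = Tr)
  if (outcome_type == "survival") {
    tm <- as.numeric(df[[time]])
    ev <- coerce_binary(df[[event]], "event")
    if (any(tm < 0)) gmte_abort("negative follow-up times", "validation")
    out$time <- tm
    out$event <- ev
  } else {
    yv <- as.numeric(df[[y]])
    if (outcome_type == "binary" && !all(yv %in% c(0, 1))) {
      gmte_abort("binary outcome_type requires a 0/1 outcome column",
                 "validation")
    }
    out$Y <- yv
  }
  for (cv in covariates) out[[cv]] <- as.numeric(df[[cv]])
  rownames(out) <- NULL

  if (length(unique(G)) < 2L) {
    gmte_warn("only one genotype level present: every estimator will fail",
              "validation")
  }
  if (all(Tr == 0)) {
    gmte_warn("no treated rows: only the untreated genotype contrast is defined",
              "validation")
  }

  x <- structure(
    list(data = out, outcome_type = outcome_type,
         covariates = covariates, treated_only = all(Tr == 1)),
    class = "pg_data"
  )
  build_derived(x)
}

# Coerce 0/1-like input (logical, numeric, "0"/"1" strings) to integer 0/1.
coerce_binary <- function(x, what) {
  if (is.logical(x)) x <- as.integer(x)
  if (is.factor(x)) x <- as.character(x)
  if (is.character(x)) x <- suppressWarnings(as.numeric(x))
  x <- as.numeric(x)
  if (anyNA(x) || !all(x %in% c(0, 1))) {
    gmte_abort(paste0(what, " indicator is not binary 0/1 after coercion"),
               "validation")
  }
  as.integer(x)
}

#' Recompute the derived regressors of a `pg_data` object
#'
#' Called by [pg_data()]; exposed so the columns can be refreshed after manual
#' edits to `x$data`. Idempotent.
#'
#' @param x a `pg_data` object.
#' @return `x` with columns `T_star`, `T_minus`, `T_star_minus`, `T_hat_star`
#'   and (when any row is treated) `T_cat` recomputed.
#' @export
build_derived <- function(x) {
  stopifnot(inherits(x, "pg_data"))
  d <- x$data
  d$T_star <- d$T * d$G
  d$T_minus <- 1L - d$T
  d$T_star_minus <- d$T_minus * d$G
  d$T_hat_star <- ave(d$T_star, d$G)
  if (any(d$T == 1)) {
    d$T_cat <- mean(d$G[d$T == 1]) * d$T
  } else {
    d$T_cat <- NULL
  }
  x$data <- d
  x$treated_only <- all(d$T == 1)
  x
}

#' Read a pharmacogenetic dataset from delimited text
#'
#' Reads a comma- or tab-delimited file (header row required; the delimiter is
#' sniffed from the header unless `sep` is given), drops rows with missing
#' values in any mapped column (with a message stating the count), validates
#' the genotype/treatment coding and constructs a [pg_data()] object.
#'
#' @inheritParams pg_data
#' @param path path to a CSV or TSV file.
#' @param sep field delimiter; `NULL` (default) auto-detects `","` vs `"\t"`.
#' @return A validated `pg_data` object.
#' @export
read_pg_data <- function(path, g = "G", t = "T", y = "Y", time = "time",
                         event = "event", covariates = character(),
                         outcome_type = c("continuous", "binary", "survival"),
                         sep = NULL) {
  if (!file.exists(path)) gmte_abort(paste0("file not found: ", path), "io")
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >
               lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  pg_data(df, g = g, t = t, y = y, time = time, event = event,
          covariates = covariates, outcome_type = outcome_type)
}

#' Metadata of a `pg_data` object as a JSON string
#'
#' Serialises row counts, outcome type, covariate names and cell counts (never
#' the data themselves) for logging.
#'
#' @param x a `pg_data` object.
#' @return A JSON string.
#' @export
pg_data_meta <- function(x) {
  stopifnot(inherits(x, "pg_data"))
  d <- x$data
  meta <- list(
    n = nrow(d),
    outcome_type = x$outcome_type,
    covariates = x$covariates,
    treated_only = x$treated_only,
    n_treated = sum(d$T == 1),
    n_carrier = sum(d$G == 1),
    n_treated_carrier = sum(d$T_star)
  )
  as.character(jsonlite::toJSON(meta, auto_unbox = TRUE))
}

#' @export
print.pg_data <- function(x, ...) {
  d <- x$data
  cat("Pharmacogenetic dataset: ", nrow(d), " rows (",
      sum(d$T == 1), " treated, ", sum(d$G == 1), " carriers), outcome: ",
      x$outcome_type, "\n", sep = "")
  if (length(x$covariates)) {
    cat("Covariates: ", paste(x$covariates, collapse = ", "), "\n", sep = "")
  }
  if (x$treated_only) {
    cat("Treated-only dataset: only the treated-population genotype",
        "contrast (gmte1) is estimable.\n")
  }
  invisible(x)
}

#' @export
as.data.frame.pg_data <- function(x, ...) x$data
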