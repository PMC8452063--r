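# Shared fixtures and independent closed-form oracles.

# Quick constructor for small in-memory datasets.
make_pd <- function(G, T, Y, Z = NULL, outcome_type = "continuous") {
  df <- data.frame(G = G, T = T, Y = Y)
  covs <- character()
  if (!is.null(Z)) {
    Z <- as.data.frame(Z)
    if (is.null(names(Z)) || any(names(Z) == "")) names(Z) <- paste0("Z", seq_along(Z))
    df <- cbind(df, Z)
    covs <- names(Z)
  }
  suppressWarnings(pg_data(df, covariates = covs, outcome_type = outcome_type))
}

# Closed-form group-mean oracles for covariate-free continuous data.
oracle_gmte1 <- function(G, T, Y) {
  mean(Y[T == 1 & G == 1]) - mean(Y[T == 1 & G == 0])
}
oracle_gmte0 <- function(G, T, Y) {
  mean(Y[T == 0 & G == 1]) - mean(Y[T == 0 & G == 0])
}
oracle_rgmte <- function(G, T, Y) oracle_gmte1(G, T, Y) - oracle_gmte0(G, T, Y)
oracle_mr <- function(G, T, Y) {
  (mean(Y[G == 1]) - mean(Y[G == 0])) / mean(T[G == 1])
}
oracle_cat <- function(G, T, Y) {
  (mean(Y[T == 1]) - mean(Y[T == 0])) / mean(G[T == 1])
}

# Random small dataset guaranteed to populate all four G x T cells.
random_cells_data <- function(n = 60) {
  repeat {
    G <- rbinom(n, 1, 0.4)
    T <- rbinom(n, 1, 0.5)
    if (all(table(factor(G, levels = 0:1), factor(T, levels = 0:1)) >= 2)) break
  }
  list(G = G, T = T, Y = rnorm(n, mean = 1 + 0.5 * T - 0.7 * T * G))
}
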