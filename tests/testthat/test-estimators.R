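test_that("gmte1 on treated-only data is the genotype group-mean difference", {
  pd <- make_pd(G = c(1, 1, 0, 0), T = rep(1, 4), Y = c(1.5, 2.5, 3, 3))
  e <- gmte1(pd)
  expect_equal(e$beta, -1.0)
  expect_equal(e$n, 4)
})

test_that("a constant outcome yields a zero estimate with a degenerate SE", {
  pd <- make_pd(G = c(1, 1, 0, 0, 1, 0), T = c(1, 1, 1, 1, 0, 0),
                Y = rep(2, 6))
  e <- suppressWarnings(gmte1(pd))
  expect_equal(e$beta, 0, tolerance = 1e-12)
  expect_lt(e$se, 1e-7)
})

test_that("gmte0 is the untreated genotype group-mean difference", {
  pd <- make_pd(G = c(1, 1, 0, 0, 1, 0), T = c(1, 0, 0, 0, 0, 1),
                Y = c(9, 1.2, 1.0, 1.0, 1.2, 9))
  e <- gmte0(pd)
  expect_equal(e$beta, 0.2)
})

test_that("gmte_cat rescales the as-treated difference by the carrier share", {
  # treated mean 4, untreated mean 3, half the treated are carriers
  pd <- make_pd(G = c(1, 0, 1, 0, 0, 0), T = c(1, 1, 1, 1, 0, 0),
                Y = c(4, 4, 4, 4, 3, 3))
  suppressWarnings(e <- gmte_cat(pd))
  expect_equal(e$beta, (4 - 3) / 0.5)

  # all treated are carriers: no rescaling
  set.seed(1)
  Y <- rnorm(40)
  G <- rep(c(1, 0), each = 20)
  T <- G
  pd2 <- make_pd(G, T, Y)
  suppressWarnings(e2 <- gmte_cat(pd2))
  expect_equal(e2$beta, mean(Y[T == 1]) - mean(Y[T == 0]))
})

test_that("gmte_mr equals the Wald ratio and its denominator is E[T|G=1]", {
  set.seed(42)
  for (i in 1:10) {
    d <- random_cells_data()
    pd <- make_pd(d$G, d$T, d$Y)
    dd <- pd$data
    expect_equal(mean(dd$T_star[dd$G == 1]) - mean(dd$T_star[dd$G == 0]),
                 mean(dd$T[dd$G == 1]))
  }
  # hand example: E[Y|G=1]-E[Y|G=0] = -0.2, E[T|G=1] = 0.4 -> -0.5
  G <- rep(c(1, 0), each = 10)
  T <- c(rep(1, 4), rep(0, 6), rep(1, 5), rep(0, 5))
  Y <- ifelse(G == 1, 0.8, 1.0)
  Y[1] <- Y[1] + 0  # constant within groups keeps the ratio exact
  pd <- make_pd(G, T, Y)
  suppressWarnings(e <- gmte_mr(pd))
  expect_equal(e$beta, -0.2 / 0.4)
})

test_that("all five estimators match their closed-form group-mean oracles", {
  set.seed(7)
  for (i in 1:25) {
    d <- random_cells_data()
    pd <- make_pd(d$G, d$T, d$Y)
    expect_equal(gmte1(pd)$beta, oracle_gmte1(d$G, d$T, d$Y), tolerance = 1e-10)
    expect_equal(gmte0(pd)$beta, oracle_gmte0(d$G, d$T, d$Y), tolerance = 1e-10)
    expect_equal(rgmte(pd)$beta, oracle_rgmte(d$G, d$T, d$Y), tolerance = 1e-10)
    suppressWarnings({
      expect_equal(gmte_mr(pd)$beta, oracle_mr(d$G, d$T, d$Y), tolerance = 1e-10)
      expect_equal(gmte_cat(pd)$beta, oracle_cat(d$G, d$T, d$Y), tolerance = 1e-10)
    })
  }
})

test_that("rgmte difference and regression routes agree", {
  set.seed(11)
  # exact identity without covariates
  for (i in 1:10) {
    d <- random_cells_data(n = 80)
    pd <- make_pd(d$G, d$T, d$Y)
    e_reg <- rgmte(pd, method = "regression")
    e_diff <- rgmte(pd, method = "difference")
    expect_equal(e_reg$beta, e_diff$beta, tolerance = 1e-8)
  }
  # with covariates the joint model pools covariate slopes across treatment
  # groups; the routes agree to a small fraction of the SE
  for (i in 1:5) {
    d <- random_cells_data(n = 400)
    Z <- rnorm(400)
    pd <- make_pd(d$G, d$T, d$Y + 0.5 * Z, Z = data.frame(Z = Z))
    e_reg <- rgmte(pd, method = "regression")
    e_diff <- rgmte(pd, method = "difference")
    expect_lt(abs(e_reg$beta - e_diff$beta), 0.05 * e_reg$se)
  }
})

test_that("p-values are consistent with the two-sided normal test", {
  set.seed(3)
  d <- random_cells_data()
  pd <- make_pd(d$G, d$T, d$Y)
  for (e in list(gmte1(pd), gmte0(pd), rgmte(pd))) {
    expect_equal(e$p, 2 * pnorm(-abs(e$beta / e$se)), tolerance = 1e-9)
    expect_gt(e$se, 0)
  }
})

test_that("estimators raise coded errors on degenerate designs", {
  # no treated carriers
  pd <- make_pd(G = c(1, 1, 0, 0, 0, 0), T = c(0, 0, 1, 1, 0, 0), Y = rnorm(6))
  expect_error(gmte1(pd), class = "gmte_error_singular")
  expect_error(gmte_cat(pd), class = "gmte_error_singular")

  # constant genotype: no instrument
  pdg <- suppressWarnings(pg_data(data.frame(G = rep(1, 6),
                                             T = c(1, 1, 1, 0, 0, 0),
                                             Y = rnorm(6))))
  expect_error(gmte_mr(pdg), class = "gmte_error_weak_instrument")

  # treated-only data only supports gmte1
  pdt <- make_pd(G = c(1, 1, 0, 0), T = rep(1, 4), Y = rnorm(4))
  expect_error(gmte0(pdt), class = "gmte_error_singular")
  expect_error(rgmte(pdt), class = "gmte_error_singular")
  expect_error(gmte_cat(pdt), class = "gmte_error_singular")

  # fit_gmte degrades gracefully instead of failing
  fits <- suppressMessages(fit_gmte(pdt))
  expect_null(fits$CAT)
  expect_s3_class(fits$GMTE1, "gmte_estimate")
})

test_that("few treated carriers triggers the weak-instrument warning", {
  G <- c(rep(1, 12), rep(0, 28))
  T <- c(1, rep(0, 11), rep(1, 14), rep(0, 14))
  pd <- make_pd(G, T, rnorm(40))
  expect_warning(gmte_mr(pd), class = "gmte_warning_weak_instrument")
})

test_that("robust SEs are available and close to model-based ones here", {
  set.seed(19)
  d <- random_cells_data(n = 300)
  pd <- make_pd(d$G, d$T, d$Y)
  e <- gmte1(pd)
  er <- gmte1(pd, robust = TRUE)
  expect_equal(e$beta, er$beta, tolerance = 1e-10)
  expect_gt(er$se, 0)
  expect_lt(abs(er$se - e$se) / e$se, 0.5)
})
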