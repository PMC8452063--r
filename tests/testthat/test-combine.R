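# Direct-formula oracle for two components.
ivw2 <- function(b1, s1, b2, s2) {
  w1 <- 1 / s1^2; w2 <- 1 / s2^2
  pooled <- (w1 * b1 + w2 * b2) / (w1 + w2)
  list(beta = pooled, se = 1 / sqrt(w1 + w2),
       Q = (b1 - b2)^2 / (s1^2 + s2^2))
}

test_that("inverse-variance pooling matches the direct formula", {
  set.seed(77)
  for (i in 1:20) {
    b <- rnorm(2); s <- runif(2, 0.05, 0.5)
    cmb <- ivw_combine(data.frame(label = c("A", "B"), beta = b, se = s))
    o <- ivw2(b[1], s[1], b[2], s[2])
    expect_equal(cmb$beta, o$beta, tolerance = 1e-12)
    expect_equal(cmb$se, o$se, tolerance = 1e-12)
    expect_equal(cmb$Q, o$Q, tolerance = 1e-10)
    expect_equal(cmb$Q_p, pchisq(o$Q, 1, lower.tail = FALSE))
    # pooled estimate lies within the component range, se below the minimum
    expect_gte(cmb$beta, min(b) - 1e-12)
    expect_lte(cmb$beta, max(b) + 1e-12)
    expect_lte(cmb$se, min(s))
  }
})

test_that("pooling the printed antiplatelet results reproduces 0.3", {
  cmb <- ivw_combine(data.frame(label = c("RGMTE", "MR"),
                                beta = c(0.33, 0.29), se = c(0.16, 0.11)))
  expect_equal(round(cmb$beta, 1), 0.3)
  expect_true(cmb$pass)
  # Q from the rounded published inputs; the source reports 0.05 from
  # unrounded ones
  expect_equal(cmb$Q, 0.042, tolerance = 0.02)
})

test_that("pooling the printed statin results reproduces -0.014", {
  cmb <- ivw_combine(data.frame(label = c("RGMTE", "MR"),
                                beta = c(-0.037, 0.0069),
                                se = c(0.018, 0.017)))
  expect_equal(round(cmb$beta, 3), -0.014)
})

test_that("identical components pool degenerately", {
  cmb <- ivw_combine(data.frame(label = c("A", "B"),
                                beta = c(0.4, 0.4), se = c(0.2, 0.2)))
  expect_equal(cmb$beta, 0.4)
  expect_equal(cmb$Q, 0)
  expect_equal(cmb$Q_p, 1)
  expect_equal(cmb$se, 0.2 / sqrt(2))
  expect_true(cmb$pass)
})

test_that("pooling is invariant to component order", {
  df <- data.frame(label = c("A", "B", "C"),
                   beta = c(0.1, -0.2, 0.05), se = c(0.1, 0.2, 0.15))
  a <- ivw_combine(df)
  b <- ivw_combine(df[c(3, 1, 2), ])
  expect_equal(a$beta, b$beta)
  expect_equal(a$Q, b$Q)
  expect_equal(a$Q_df, 2L)
})

test_that("invalid combinations raise coded errors", {
  expect_error(ivw_combine(data.frame(label = "A", beta = 1, se = 1)),
               class = "gmte_error_combine")
  expect_error(ivw_combine(data.frame(label = letters[1:4], beta = 1:4,
                                      se = rep(1, 4))),
               class = "gmte_error_combine")
  expect_error(ivw_combine(data.frame(label = c("A", "B"), beta = 1:2,
                                      se = c(1, 0))),
               class = "gmte_error_validation")
  expect_error(ivw_combine(data.frame(label = c("A", "B"), beta = 1:2,
                                      se = c(1, 1)), alpha = 2),
               class = "gmte_error_validation")
})

test_that("triangulation returns the nine sanctioned results", {
  tab <- triangulate(data.frame(
    label = c("CAT", "GMTE1", "MR", "RGMTE"),
    beta = c(2.2, 0.28, 0.29, 0.33),
    se = c(0.21, 0.14, 0.11, 0.16)
  ))$table
  expect_equal(nrow(tab), 9)
  expect_setequal(tab$label[tab$kind == "combined"],
                  c("CAT/GMTE1", "CAT/RGMTE", "CAT/MR", "RGMTE/MR",
                    "CAT/RGMTE/MR"))
  # correlated pairs are never formed
  expect_false(any(grepl("GMTE1/RGMTE|GMTE1/MR|RGMTE/GMTE1|MR/GMTE1",
                         tab$label)))
  # with the printed antiplatelet inputs only RGMTE/MR is homogeneous
  passing <- tab$label[tab$kind == "combined" & tab$pass]
  expect_equal(passing, "RGMTE/MR")
})

test_that("identical single estimates make every combination pass with Q = 0", {
  tab <- triangulate(data.frame(
    label = c("CAT", "GMTE1", "MR", "RGMTE"),
    beta = rep(-0.5, 4), se = rep(0.1, 4)
  ))$table
  comb <- tab[tab$kind == "combined", ]
  expect_true(all(comb$pass))
  expect_true(all(comb$Q == 0))
})

test_that("a missing single estimate is reported as unavailable", {
  tab <- triangulate(data.frame(
    label = c("CAT", "GMTE1", "RGMTE"),
    beta = c(1, 0.5, 0.4), se = c(0.2, 0.1, 0.1)
  ))$table
  expect_equal(nrow(tab), 9)
  unavailable <- tab$label[!tab$available]
  expect_setequal(unavailable, c("MR", "CAT/MR", "RGMTE/MR", "CAT/RGMTE/MR"))
  expect_true(all(is.na(tab$beta[!tab$available])))
})

test_that("estimate objects refuse to pool across scales", {
  e1 <- structure(list(label = "RGMTE", beta = 0.1, se = 0.1, p = 0.3,
                       n = 10L, assumptions = "", scale = "mean_difference",
                       percent = FALSE), class = "gmte_estimate")
  e2 <- e1; e2$label <- "MR"; e2$scale <- "risk_difference"
  expect_error(ivw_combine(list(e1, e2)), class = "gmte_error_scale")
})
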