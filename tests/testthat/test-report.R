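test_that("avoided-event counts reproduce the published worked examples", {
  # antiplatelet example: 5,264 carrier patient-years
  expect_equal(avoided_events(0.33, 0.16, 5264)$count, 17)
  expect_equal(avoided_events(0.30, 0.089, 5264)$count, 16)
  expect_equal(avoided_events(0.28, 0.14, 5264)$count, 15)
  # statin example: 278,409 patient-years
  expect_equal(avoided_events(0.037, 0.018, 278409)$count, 103)
  expect_equal(avoided_events(0.046, 0.011, 278409)$count, 128)
  expect_equal(avoided_events(0.014, 0.013, 278409)$count, 39)
})

test_that("avoided-event arithmetic rounds half away from zero at the end", {
  # 0.5% over 100 person-years is exactly half an event
  expect_equal(avoided_events(0.5, person_years = 100)$count, 1)
  expect_equal(avoided_events(-0.5, person_years = 100)$count, -1)
  expect_equal(avoided_events(-0.5, person_years = 100)$magnitude, 1)
  expect_equal(avoided_events(0, 0.1, 1000)$count, 0)
  # linear in person-years before rounding
  a <- avoided_events(0.2, person_years = 1000)$count
  b <- avoided_events(0.2, person_years = 2000)$count
  expect_equal(b, 2 * a)
  # interval from the printed statin inputs, same rounding rule
  ae <- avoided_events(0.037, 0.018, 278409)
  expect_equal(ae$lower, 5)
  expect_equal(ae$upper, 201)
  expect_error(avoided_events(0.1, 0.1, 0), class = "gmte_error_validation")
  expect_error(avoided_events(0.1, -1, 10), class = "gmte_error_validation")
})

test_that("forest plots colour-code the heterogeneity gate", {
  tri <- triangulate(data.frame(
    label = c("CAT", "GMTE1", "MR", "RGMTE"),
    beta = c(2.2, 0.28, 0.29, 0.33),
    se = c(0.21, 0.14, 0.11, 0.16)
  ))
  p <- forest_plot(tri)
  expect_s3_class(p, "ggplot")
  classes <- p$data$class
  expect_equal(sum(p$data$class == "combined (fail)"), 4)
  # one combined estimate passes, so 4 singles + 1 pass share the first class
  expect_equal(sum(p$data$class == "estimate / combined (pass)"), 5)

  # falsification estimate gets its own class
  e0 <- structure(list(label = "GMTE0", beta = -0.0039, se = 0.0075,
                       p = 0.61, n = 100L, assumptions = "",
                       scale = "summary", percent = NA),
                  class = "gmte_estimate")
  p2 <- forest_plot(tri, gmte0 = e0)
  expect_equal(sum(p2$data$class == "falsification"), 1)

  # deterministic layout and writable output
  f <- file.path(tempdir(), "forest.pdf")
  forest_plot(tri, file = f)
  expect_true(file.exists(f))
  unlink(f)
  expect_error(forest_plot(tri$table[0, ]), class = "gmte_error_validation")
})

test_that("the pipeline runs end to end on a simulated dataset", {
  cfg <- scenario_preset(3, n = 6000, seed = 15)
  pd <- simulate_gmte(cfg, seed = 303)
  bundle <- suppressMessages(gmte_pipeline(pd))
  expect_s3_class(bundle, "gmte_bundle")
  expect_equal(nrow(bundle$estimates), 5)
  expect_equal(nrow(bundle$triangulation), 9)
  expect_true(all(bundle$triangulation$available))
  # under a PG1-only violation every sanctioned combination is homogeneous
  comb <- bundle$triangulation[bundle$triangulation$kind == "combined", ]
  expect_gte(sum(comb$pass), 4)
  expect_equal(nrow(bundle$diagnostics), 5)

  dir <- file.path(tempdir(), "bundle-out")
  paths <- write_bundle(bundle, dir)
  expect_true(all(file.exists(paths)))
  # identical inputs produce identical serialised bundles
  first <- readLines(paths["json"])
  write_bundle(bundle, dir)
  expect_identical(readLines(paths["json"]), first)
  unlink(dir, recursive = TRUE)
})

test_that("summary-level pipeline input reproduces a published combined row", {
  tab <- triangulate(data.frame(
    label = c("CAT", "GMTE1", "MR", "RGMTE"),
    beta = c(2.2, 0.28, 0.29, 0.33),
    se = c(0.21, 0.14, 0.11, 0.16)
  ))$table
  row <- tab[tab$label == "RGMTE/MR", ]
  expect_equal(round(row$beta, 1), 0.3)
  expect_equal(row$se, 0.089, tolerance = 0.02)
  expect_true(row$pass)
})

test_that("pipeline propagates stage-tagged validation errors", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(G = c(0, 1), T = c(1, 0), X = 1:2), f,
            row.names = FALSE)
  expect_error(suppressMessages(gmte_pipeline(f)),
               class = "gmte_error_validation")
  unlink(f)
})
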