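test_that("the wrist pair defines the physical scale", {
  mk <- function(a, b) {
    co <- matrix(NA_real_, 6, 2); co[2, ] <- a; co[6, ] <- b
    LandmarkSet(co)
  }
  expect_equal(normalizationConstant(mk(c(0, 0), c(0, 50))), 1.0)
  expect_equal(normalizationConstant(mk(c(0, 0), c(0, 100))), 0.5)
  expect_equal(normalizationConstant(mk(c(3, 4), c(0, 0))), 10.0)
  expect_error(normalizationConstant(mk(c(5, 5), c(5, 5))), "degenerate")
  co <- matrix(NA_real_, 6, 2); co[2, ] <- c(0, 0)
  expect_error(normalizationConstant(LandmarkSet(co)), "present")
})

test_that("point errors scale Euclidean distance to millimetres", {
  expect_equal(pointError(c(7, 9), c(7, 9), 2.5), 0)
  expect_equal(pointError(c(10, 10), c(10, 14), 0.5), 2.0)
  expect_equal(pointError(c(1, 1), c(4, 5), 1), 5.0)
  # symmetry and linear scaling
  set.seed(3)
  for (k in 1:20) {
    a <- runif(2, 0, 100); b <- runif(2, 0, 100); s <- runif(1, 0.1, 3)
    expect_equal(pointError(a, b, s), pointError(b, a, s))
    expect_equal(pointError(a, b, 2 * s), 2 * pointError(a, b, s))
  }
  expect_error(pointError(c(0, 0), c(1, 1), -1), "positive")
})

test_that("error summaries count strict outliers and basic statistics", {
  s <- summarizeErrors(c(1.9, 2.1, 4.1, 10.5), c(2, 4, 10))
  expect_equal(unname(s@outlierCounts), c(3, 2, 1))
  expect_equal(s@nPredictions, 4L)
  expect_equal(s@medianMm, median(c(1.9, 2.1, 4.1, 10.5)))
  expect_equal(s@sdMm, sd(c(1.9, 2.1, 4.1, 10.5)))    # sample sd (n - 1)
  # boundary value exactly at the radius is not an outlier
  sb <- summarizeErrors(c(2, 4, 10))
  expect_equal(unname(sb@outlierCounts), c(2, 1, 0))
  z <- summarizeErrors(rep(0, 5))
  expect_equal(z@medianMm, 0); expect_equal(z@meanMm, 0)
  expect_equal(unname(z@outlierCounts), c(0, 0, 0))
  expect_error(summarizeErrors(numeric(0)), "empty")
})

test_that("summaries are permutation invariant", {
  set.seed(11)
  e <- rexp(200, 1 / 3)
  a <- summarizeErrors(e); b <- summarizeErrors(sample(e))
  expect_equal(a@meanMm, b@meanMm)
  expect_equal(a@outlierCounts, b@outlierCounts)
})

test_that("count-to-percent arithmetic matches at the reported precision", {
  expect_equal(outlierPercent(1572, 33115), 4.75)
  expect_equal(outlierPercent(4, 100, 1), 4.0)
})

test_that("metric reports round-trip through CSV and JSON", {
  s <- summarizeErrors(c(0.5, 1.5, 2.5, 11))
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  tab <- writeMetricsReport(s, csv, js)
  back <- read.csv(csv)
  expect_equal(back$value[back$metric == "mean_mm"], s@meanMm)
  j <- jsonlite::read_json(js)
  expect_equal(j$n_predictions, 4L)
})

test_that("per-landmark error tables mask invisible target landmarks", {
  co <- rbind(c(0, 0), c(0, 50), c(10, 10))
  t1 <- LandmarkSet(co, c(TRUE, TRUE, FALSE), "imgA")
  p1 <- LandmarkSet(co + 1)
  tab <- perLandmarkErrorTable(list(p1), list(t1), scales = 1)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$pe_mm, rep(sqrt(2), 2))
})
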