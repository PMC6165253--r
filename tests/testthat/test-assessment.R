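test_that("confusion counts enumerate pixels as hand-counted", {
  legend <- c(`1` = "a", `2` = "b")
  pred <- classMap(matrix(c(1, 1, 2, 2, 1, 0, 2, 1, 1), 3, 3), legend)
  ref <- classMap(matrix(c(1, 2, 2, 2, 1, 1, 2, 2, 1), 3, 3), legend)
  cm <- confusionCounts(pred, ref)
  ## by hand over the 8 shared valid pixels:
  ## (pred,ref): (1,1) (1,2) (2,2) (2,2) (1,1) (2,2) (1,2) (1,1)
  expect_equal(unname(confusionCountsOf(cm)),
               matrix(c(3, 0, 2, 3), 2, 2), ignore_attr = TRUE)
  ## identical maps give a diagonal matrix
  cm2 <- confusionCounts(pred, pred)
  expect_true(all(confusionCountsOf(cm2)[upper.tri(diag(2))] == 0))
  ## disjoint masks are an error
  p2 <- classMap(matrix(c(1, 0, 0, 0), 2, 2), legend)
  r2 <- classMap(matrix(c(0, 2, 2, 0), 2, 2), legend)
  expect_error(confusionCounts(p2, r2), "empty overlap")
  ## legend mismatch is an error
  r3 <- classMap(matrix(1, 3, 3), c(`1` = "other"))
  expect_error(confusionCounts(pred, r3), "legend")
})

test_that("metrics satisfy their defining identities", {
  cm <- confusionMatrix(matrix(c(50, 5, 3, 42), 2, 2, byrow = TRUE),
                        c(`1` = "a", `2` = "b"))
  r <- accuracyMetrics(cm)
  tot <- 100
  expect_equal(r$overallAccuracy, 92 / 100)
  expect_equal(r$ua[["a"]], 50 / 55)
  expect_equal(r$pa[["a"]], 50 / 53)
  pe <- (55 * 53 + 45 * 47) / tot^2
  expect_equal(r$kappa, (0.92 - pe) / (1 - pe))
  ## rate identities: TP+FN = 1 and TN+FP = 1 per class
  expect_equal(unname(r$tpRate + r$fnRate), c(1, 1))
  expect_equal(unname(r$tnRate + r$fpRate), c(1, 1))
  expect_equal(r$fpRate[["a"]], 5 / (100 - 53))
  ## perfect diagonal -> OA = kappa = UA = PA = 1
  perfect <- accuracyMetrics(confusionMatrix(diag(c(10, 20, 30)),
                                             c(`1` = "a", `2` = "b", `3` = "c")))
  expect_equal(perfect$overallAccuracy, 1)
  expect_equal(perfect$kappa, 1)
  expect_true(all(perfect$ua == 1) && all(perfect$pa == 1))
  ## kappa = 1 iff OA = 1 for nondegenerate marginals
  expect_lt(r$kappa, 1)
})

test_that("empty rows or columns are flagged, not NaN-propagated", {
  m <- matrix(c(10, 5, 2, 0, 0, 0, 0, 0, 8), 3, 3, byrow = TRUE)
  cm <- confusionMatrix(m, c(`1` = "a", `2` = "b", `3` = "c"))
  r <- accuracyMetrics(cm)
  expect_true(is.na(r$ua[["b"]]))       # empty classified row
  expect_true("b" %in% r$undefined)
  expect_false(any(is.nan(unlist(r[c("ua", "pa", "fpRate")]))))
})

test_that("permuting the class order permutes the report consistently", {
  set.seed(61)
  m <- matrix(rpois(16, 40), 4, 4)
  legend <- stats::setNames(c("w", "x", "y", "z"), 1:4)
  r1 <- accuracyMetrics(confusionMatrix(m, legend))
  p <- c(3, 1, 4, 2)
  r2 <- accuracyMetrics(confusionMatrix(m[p, p], legend[p]))
  expect_equal(r2$overallAccuracy, r1$overallAccuracy)
  expect_equal(r2$kappa, r1$kappa)
  expect_equal(r2$ua[names(r1$ua)], r1$ua)
  expect_equal(r2$pa[names(r1$pa)], r1$pa)
})

test_that("confusion CSV round trips through the legend-labeled format", {
  m <- matrix(c(7, 1, 2, 9), 2, 2)
  cm <- confusionMatrix(m, c(`1` = "a", `2` = "b"))
  f <- tempfile(fileext = ".csv")
  writeConfusionCsv(cm, f)
  back <- readConfusionCsv(f)
  expect_equal(unname(confusionCountsOf(back)), unname(m))
  expect_equal(unname(classLegend(back)), c("a", "b"))
})

test_that("the shipped reference confusion matrix is internally consistent", {
  cm <- readConfusionCsv(system.file("extdata", "reference_confusion_counts.csv",
                                     package = "polcropsar"))
  ref <- utils::read.csv(system.file("extdata", "reference_testing_counts.csv",
                                     package = "polcropsar"))
  cs <- colSums(confusionCountsOf(cm))
  ## column sums match the published per-class testing-pixel counts; the
  ## source tables themselves disagree by 6 (Watermelon) and 4 (Forest)
  ## pixels, so those two are checked at the published discrepancy
  exact <- c("Water", "Rice1", "Rice2", "Lotus", "BareSoil", "Grass")
  expect_equal(unname(cs[exact]),
               ref$testing_pixels[match(exact, ref$class)])
  expect_equal(unname(cs["Water"]), 241174)
  expect_true(all(abs(cs - ref$testing_pixels[match(names(cs), ref$class)]) <= 6))
})
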