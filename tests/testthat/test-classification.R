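test_that("Wishart training recovers exact and simulated class means", {
  ## all training pixels share one matrix -> the class mean is that matrix
  v1 <- c(1, 0.5, 1, rep(0, 6))
  v2 <- c(4, 2, 4, rep(0, 6))
  rows <- rbind(matrix(rep(v1, 10), 10, byrow = TRUE),
                matrix(rep(v2, 10), 10, byrow = TRUE))
  fld <- rowsToField(rows)
  tr <- trainingSet(data.frame(row = 1, col = 1:20,
                               classId = rep(1:2, each = 10)),
                    c(`1` = "a", `2` = "b"))
  m <- wishartTrain(fld, tr)
  expect_equal(m@sigma[[1]], paramsToC3Matrix(v1), tolerance = 1e-12)
  expect_equal(m@sigma[[2]], paramsToC3Matrix(v2), tolerance = 1e-12)
  for (S in m@sigma)
    expect_equal(max(abs(S - Conj(t(S)))), 0, tolerance = 1e-12)
  expect_equal(m@epsilon, 0)
  ## a rank-deficient class mean triggers the diagonal loading
  vs <- sinclairParams(1, 0, 1)          # rank-1 point target
  fld2 <- rowsToField(rbind(matrix(rep(vs, 10), 10, byrow = TRUE),
                            matrix(rep(v2, 10), 10, byrow = TRUE)))
  m2 <- wishartTrain(fld2, tr)
  expect_gt(m2@epsilon, 0)
  expect_gt(Mod(polcropsar:::.cdet3(m2@sigma[[1]])), 0)
})

test_that("Wishart sample means converge to the generating covariance", {
  Sig <- matrix(c(1, 0.2 + 0.1i, 0.5, 0.2 - 0.1i, 0.4, 0.1i,
                  0.5, -0.1i, 1.2), 3, 3, byrow = TRUE)
  X <- sampleWishartC3(Sig, L = 4, n = 2000, seed = 17)
  fld <- rowsToField(X, looks = 4)
  tr <- trainingSet(data.frame(row = 1, col = 1:2000,
                               classId = rep(1:2, 1000)),
                    c(`1` = "a", `2` = "b"))
  m <- wishartTrain(fld, tr)
  for (S in m@sigma) {
    relErr <- frobNorm(S - Sig) / frobNorm(Sig)
    expect_lt(relErr, 0.05)
  }
})

test_that("Wishart distance assigns the generating class on a separated toy model", {
  ## class means with Frobenius separation far above within-class spread
  s1 <- diag(c(1, 0.5, 1)); s2 <- diag(c(40, 20, 40))
  legend <- c(`1` = "low", `2` = "high")
  model <- new("WishartModel", sigma = list(s1 + 0i, s2 + 0i),
               counts = c(10L, 10L), epsilon = 0, legend = legend)
  fld <- pixelField(c(1, 0.5, 1, rep(0, 6)), c(40, 20, 40, rep(0, 6)))
  map <- wishartClassify(fld, model)
  expect_equal(as.vector(classLabels(map)), 1:2)
  ## direct distance evaluation agrees: d_m(Sigma_m) is the minimum
  d <- function(S, C) Re(log(det(S)) + sum(diag(solve(S) %*% C)))
  expect_lt(d(s1, s1), d(s2, s1))
  expect_lt(d(s2, s2), d(s1, s2))
})

test_that("identical class means tie-break to the lowest class id", {
  s <- diag(c(1, 1, 1)) + 0i
  model <- new("WishartModel", sigma = list(s, s), counts = c(9L, 9L),
               epsilon = 0, legend = c(`1` = "a", `2` = "b"))
  set.seed(19)
  fld <- do.call(pixelField, lapply(1:20, function(i) randomPsdParams()))
  map <- wishartClassify(fld, model)
  expect_true(all(classLabels(map) == 1L))
})

test_that("Wishart classification is invariant to a global scale", {
  set.seed(23)
  X1 <- sampleWishartC3(diag(c(1, 0.5, 1)), 4, 200)
  X2 <- sampleWishartC3(diag(c(3, 1, 2)), 4, 200)
  fld <- rowsToField(rbind(X1, X2), looks = 4)
  tr <- trainingSet(data.frame(row = 1, col = 1:400,
                               classId = rep(1:2, each = 200)),
                    c(`1` = "a", `2` = "b"))
  m <- wishartTrain(fld, tr)
  map1 <- wishartClassify(fld, m)
  ## scale both the data and the model by 100
  fldS <- c3Field(fld@data * 100, looks = 4)
  mS <- m
  mS@sigma <- lapply(m@sigma, function(S) S * 100)
  map2 <- wishartClassify(fldS, mS)
  expect_identical(classLabels(map1), classLabels(map2))
})

test_that("SVM separates Gaussian blobs and honors its contracts", {
  set.seed(3)
  n <- 200
  x <- rbind(cbind(rnorm(n / 2, -2), rnorm(n / 2, -2)),
             cbind(rnorm(n / 2, 2), rnorm(n / 2, 2)))
  x01 <- (x + 6) / 12
  arr <- array(x01, c(1, n, 2), list(NULL, NULL, c("f1", "f2")))
  st <- minmaxNormalize(featureStack(arr))
  tr <- trainingSet(data.frame(row = 1, col = 1:n,
                               classId = rep(1:2, each = n / 2)),
                    c(`1` = "a", `2` = "b"))
  h <- svmTrain(st, tr, seed = 3)
  expect_gt(h$cvAccuracy, 0.95)
  map <- svmPredict(st, h)
  pred <- classLabels(map)[cbind(tr@pixels$row, tr@pixels$col)]
  trainAcc <- mean(pred == tr@pixels$classId)
  expect_gte(trainAcc, 0.95)
  expect_gte(trainAcc, h$cvAccuracy - 1e-9)
  ## refit with the same seed/config is bit-identical
  h2 <- svmTrain(st, tr, seed = 3)
  expect_identical(classLabels(svmPredict(st, h2)), classLabels(map))
  ## permuting layer order with correct names gives identical output
  perm <- featureStack(array(st@data[, , 2:1], c(1, n, 2),
                             list(NULL, NULL, c("f2", "f1"))),
                       normalization = st@normalization[2:1])
  expect_identical(classLabels(svmPredict(perm, h)), classLabels(map))
  ## layer mismatch is an error listing the difference
  bad <- featureStack(array(st@data, c(1, n, 2),
                            list(NULL, NULL, c("f1", "zz"))))
  expect_error(svmPredict(bad, h), "zz")
  ## empty mask -> all-nodata map
  empty <- st
  empty@mask[] <- FALSE
  expect_true(all(classLabels(svmPredict(empty, h)) == 0L))
})

test_that("degenerate single-class SVM input is an error", {
  arr <- array(runif(40), c(1, 20, 2), list(NULL, NULL, c("f1", "f2")))
  st <- featureStack(arr)
  expect_error(
    trainingSet(data.frame(row = 1, col = 1:20, classId = 1),
                c(`1` = "a")),
    "2 classes")
})

test_that("integrated features beat either single source on the default scene", {
  ## classes built so one pair is separable only polarimetrically and one
  ## pair only spectrally: integration must dominate both single sources
  sc <- tinyScene(seed = 42)
  sarFs <- buildSarFeatures(sc$c3)
  optFs <- buildOpticalFeatures(sc$optical)
  oa <- function(mode) {
    st <- assembleFeatures(mode, sarFs, optFs)
    h <- svmTrain(st, sc$train, cost = c(1, 10), gamma = c(0.1, 1),
                  folds = 3, seed = 42)
    accuracyMetrics(confusionCounts(svmPredict(st, h), sc$test))$overallAccuracy
  }
  full <- oa("full")
  expect_gte(full, oa("sar_only"))
  expect_gte(full, oa("optical_only"))
})
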