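test_that("min-max normalization maps layers affinely onto [0, 1]", {
  m <- matrix(c(-50, 0, 50, 25), 2, 2)
  st <- featureStack(list(a = m, b = matrix(c(0, 1, 1, 0), 2, 2)))
  norm <- minmaxNormalize(st)
  expect_equal(layerData(norm, "a"), matrix(c(0, 0.5, 1, 0.75), 2, 2))
  ## a layer already in {0,1} is unchanged
  expect_equal(layerData(norm, "b"), matrix(c(0, 1, 1, 0), 2, 2))
  ## idempotence
  norm2 <- minmaxNormalize(norm)
  expect_equal(norm2@data, norm@data)
})

test_that("zero-range layers normalize to 0 with a warning", {
  st <- featureStack(list(flat = matrix(3, 2, 2), ok = matrix(1:4, 2, 2)))
  expect_warning(norm <- minmaxNormalize(st), "zero range")
  expect_true(all(layerData(norm, "flat") == 0))
})

test_that("robust normalization clips at the percentile bounds", {
  set.seed(31)
  m <- matrix(rnorm(10000), 100, 100)
  m[1] <- 1e6                       # one gross outlier
  st <- featureStack(list(x = m))
  plain <- minmaxNormalize(st)
  robust <- minmaxNormalize(st, robust = TRUE)
  ## the outlier squashes the plain scaling but not the robust one
  expect_lt(stats::median(layerData(plain, "x")), 0.01)
  expect_gt(stats::median(layerData(robust, "x")), 0.3)
  v <- layerData(robust, "x")
  expect_true(all(v >= 0 & v <= 1))
})

test_that("stored normalization constants reapply to a second scene", {
  st <- featureStack(list(a = matrix(c(0, 5, 10, 5), 2, 2)))
  norm <- minmaxNormalize(st)
  st2 <- featureStack(list(a = matrix(c(2.5, 20, -5, 5), 2, 2)))
  norm2 <- minmaxNormalize(st2, constants = norm@normalization)
  expect_equal(layerData(norm2, "a"), matrix(c(0.25, 1, 0, 0.5), 2, 2))
})

test_that("sigma PCA matches an independent eigendecomposition of the channel covariance", {
  sc <- tinyScene(seed = 7)
  s <- intensityToDb(c3ToIntensity(sc$c3))
  fit <- sigmaPCA(s, varThreshold = 0.98)
  info <- pcaInfo(fit)
  X <- matrix(s@data, prod(dim(s@data)[1:2]), 9)
  ev <- eigen(stats::cov(X), symmetric = TRUE)$values
  expect_equal(unname(info$explained), ev / sum(ev), tolerance = 1e-8)
  sc12 <- matrix(layerData(fit), ncol = info$kept)[, 1:2]
  expect_lt(abs(cor(sc12[, 1], sc12[, 2])), 1e-8)
  ## nine identical channels collapse to one component at 100% variance
  flat <- s
  flat@data <- array(rep(s@data[, , 1], 9), dim(s@data),
                     dimnames = dimnames(s@data))
  one <- sigmaPCA(flat)
  expect_equal(pcaInfo(one)$kept, 1L)
  expect_equal(pcaInfo(one)$explained[1], 1, tolerance = 1e-10)
})

test_that("integration modes assemble exactly the documented layer sets", {
  sc <- tinyScene(seed = 8)
  sarFs <- buildSarFeatures(sc$c3)
  optFs <- buildOpticalFeatures(sc$optical)
  st <- assembleFeatures("full", sarFs, optFs)
  expect_equal(dim(st@data)[3], 11L)
  expect_setequal(layerNames(st),
                  c("sigma_pca1", "sigma_pca2", "RVI", "Ps", "Pd", "Ph", "Pv",
                    "Opband_pca1", "Opband_pca2", "NDVI", "H"))
  st2 <- assembleFeatures("sar7_opt2", sarFs, optFs)
  expect_equal(dim(st2@data)[3], 9L)
  expect_setequal(intersect(layerNames(st2), c("NDVI", "H")), c("NDVI", "H"))
  expect_false(any(grepl("^Opband", layerNames(st2))))
  st3 <- assembleFeatures("sar5_opt4", sarFs, optFs)
  expect_equal(dim(st3@data)[3], 9L)
  expect_false(any(grepl("^sigma_pca", layerNames(st3))))
  ## every assembled layer lies in [0, 1] on valid pixels
  for (s in list(st, st2, st3)) {
    v <- s@data[rep(s@mask, dim(s@data)[3])]
    expect_true(all(v >= 0 & v <= 1))
  }
})

test_that("a missing layer is a config error naming it", {
  sc <- tinyScene(seed = 9)
  optFs <- buildOpticalFeatures(sc$optical)
  crippled <- featureStack(list(RVI = layerData(optFs, "NDVI")))
  expect_error(assembleFeatures("full", crippled, optFs), "sigma_pca1")
  expect_error(assembleFeatures("full", NULL, optFs), "needs sar")
})

test_that("assembled masks are conservative", {
  sc <- tinyScene(seed = 10)
  sarFs <- buildSarFeatures(sc$c3)
  optFs <- buildOpticalFeatures(sc$optical)
  optFs@mask[1:5, 1:5] <- FALSE
  st <- assembleFeatures("full", sarFs, optFs)
  expect_true(all(!st@mask[1:5, 1:5]))
  expect_true(all(st@mask <= (sarFs@mask & optFs@mask)))
})
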