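test_that("NDVI evaluates its closed form and masks zero denominators", {
  r <- matrix(c(0.2, 0.5, 0, 0), 2, 2)
  n <- matrix(c(0.6, 0.5, 1, 0), 2, 2)
  out <- ndvi(r, n)
  expect_equal(out$values[1, 1], 0.5)       # (0.6-0.2)/(0.6+0.2)
  expect_equal(out$values[2, 1], 0)         # NIR = R > 0
  expect_equal(out$values[1, 2], 1)         # bound attained
  expect_false(out$mask[2, 2])              # NIR + R = 0 -> masked
  expect_true(is.na(out$values[2, 2]))
  expect_error(ndvi(r, matrix(0, 3, 3)), "grid")
})

test_that("NDVI stays within [-1, 1] on random reflectances", {
  set.seed(10)
  r <- matrix(runif(400), 20, 20)
  n <- matrix(runif(400), 20, 20)
  v <- ndvi(r, n)$values
  expect_true(all(v >= -1 & v <= 1, na.rm = TRUE))
})

test_that("window entropy reproduces hand-computed histograms", {
  ## 7x7 image of two gray levels, 25 vs 24 pixels: at the center the window
  ## is the whole image and the two-bin entropy is exact
  img <- matrix(0, 7, 7)
  img[1:24] <- 1
  H <- entropyTexture(img, window = 7, bins = 2)$values
  expect_equal(H[4, 4],
               -(25 / 49) * log2(25 / 49) - (24 / 49) * log2(24 / 49),
               tolerance = 1e-12)
  ## window filling all k bins equally -> log2(k)
  img2 <- matrix(1:9, 3, 3)
  H2 <- entropyTexture(img2, window = 3, bins = 3)$values
  expect_equal(H2[2, 2], log2(3), tolerance = 1e-12)
  ## constant window -> 0
  H3 <- entropyTexture(matrix(c(rep(0, 40), rep(1, 60)), 10, 10),
                       window = 3, bins = 4)$values
  expect_equal(H3[2, 2], 0)
})

test_that("entropy of a constant band is zero with a warning", {
  expect_warning(out <- entropyTexture(matrix(5, 6, 6)), "constant")
  expect_true(all(out$values == 0))
})

test_that("entropy is bounded by log2(bins)", {
  set.seed(12)
  img <- matrix(rnorm(2500), 50, 50)
  for (bins in c(2, 8, 32)) {
    H <- entropyTexture(img, window = 7, bins = bins)$values
    expect_true(all(H >= 0 & H <= log2(bins) + 1e-12))
  }
})

test_that("band PCA keeps the smallest component set reaching the variance target", {
  set.seed(13)
  base <- matrix(rnorm(900), 30, 30)
  ## four exact copies of one band: rank 1, one component explains 100%
  dup <- opticalBands(array(rep(base, 4), c(30, 30, 4),
                            list(NULL, NULL, c("R", "G", "B", "NIR"))))
  fit <- bandPCA(dup, varThreshold = 0.99)
  expect_equal(pcaInfo(fit)$kept, 1L)
  expect_equal(pcaInfo(fit)$explained[1], 1, tolerance = 1e-10)
  ## two independent unit-variance bands: each explains ~50%, both kept
  two <- opticalBands(array(c(matrix(rnorm(10000), 100, 100),
                              matrix(rnorm(10000), 100, 100)),
                            c(100, 100, 2), list(NULL, NULL, c("R", "NIR"))))
  fit2 <- bandPCA(two, varThreshold = 0.99)
  expect_equal(pcaInfo(fit2)$kept, 2L)
  expect_equal(pcaInfo(fit2)$explained, c(0.5, 0.5), tolerance = 0.05)
})

test_that("PCA components are orthonormal, uncorrelated and exhaustive", {
  set.seed(14)
  arr <- array(runif(40 * 40 * 4), c(40, 40, 4),
               list(NULL, NULL, c("R", "G", "B", "NIR")))
  fit <- bandPCA(opticalBands(arr), varThreshold = 1)
  info <- pcaInfo(fit)
  L <- info$loadings
  expect_equal(max(abs(t(L) %*% L - diag(ncol(L)))), 0, tolerance = 1e-10)
  expect_equal(sum(info$explained), 1, tolerance = 1e-12)
  sc <- matrix(layerData(fit), ncol = info$kept)
  cors <- cor(sc)
  expect_true(all(abs(cors[upper.tri(cors)]) < 1e-8))
  ## sign convention: largest-magnitude loading positive
  for (j in seq_len(ncol(L)))
    expect_gt(L[which.max(abs(L[, j])), j], 0)
})
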