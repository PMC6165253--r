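## Seeded simulator of labeled PolSAR + optical scenes: multi-look speckled
## covariance pixels drawn from per-class complex Wishart models on a
## rectangular field mosaic, with class-specific truncated-Gaussian optical
## reflectances. Gives the pipeline the statistical structure it assumes,
## with exact ground truth.

.hermitianFactor <- function(Sigma, tol = 1e-10) {
  e <- eigen(Sigma, symmetric = TRUE)
  s <- sum(abs(e$values))
  if (any(e$values < -tol * max(s, 1)))
    stop("class covariance is not positive semidefinite")
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow = 3)
}

#' Sample multi-look covariance pixels from a complex Wishart model
#'
#' Each pixel is C = (1/L) sum_{k=1..L} z_k z_k^H with z_k a zero-mean
#' circular complex Gaussian of covariance Sigma, so E[C] = Sigma and the
#' per-channel intensity coefficient of variation is 1/sqrt(L).
#'
#' @param Sigma 3x3 Hermitian positive semidefinite covariance (complex or
#'   real).
#' @param L number of looks (>= 1).
#' @param n number of pixels.
#' @param seed optional RNG seed (omit to continue the current RNG stream).
#' @return numeric n x 9 matrix of C3 parameters in canonical order.
#' @export
sampleWishartC3 <- function(Sigma, L, n, seed = NULL) {
  stopifnot(L >= 1, n >= 1)
  if (!is.null(seed)) set.seed(seed)
  Sigma <- Sigma + 0i
  if (max(abs(Sigma - Conj(t(Sigma)))) > 1e-9 * max(abs(Sigma), 1e-30))
    stop("Sigma must be Hermitian")
  A <- .hermitianFactor(Sigma)
  m <- n * L
  Z <- matrix(complex(real = stats::rnorm(3 * m),
                      imaginary = stats::rnorm(3 * m)) / sqrt(2), 3, m)
  W <- A %*% Z
  w <- lapply(1:3, function(a) matrix(W[a, ], L, n))
  cc <- function(a, b) colSums(w[[a]] * Conj(w[[b]])) / L
  out <- cbind(Re(cc(1, 1)), Re(cc(2, 2)), Re(cc(3, 3)),
               Re(cc(1, 2)), Im(cc(1, 2)),
               Re(cc(1, 3)), Im(cc(1, 3)),
               Re(cc(2, 3)), Im(cc(2, 3)))
  colnames(out) <- C3_PARAMS
  out
}

.truncNorm01 <- function(n, mu, sd) {
  lo <- stats::pnorm(0, mu, sd)
  hi <- stats::pnorm(1, mu, sd)
  stats::qnorm(stats::runif(n, lo, hi), mu, sd)
}

#' Default simulated crop classes
#'
#' Four classes arranged so that one pair is separable only polarimetrically
#' and one pair only spectrally, mirroring the complementary character of the
#' two sensors: classes A and B share identical optical reflectances and
#' identical radar vegetation index / four-component signatures, differing
#' only in the real co-/cross-polarization correlations that the nine-channel
#' basis-transform intensities resolve; classes C and D share one volume-like
#' covariance and differ only in the green/blue reflectances that the optical
#' band PCA resolves (their NDVI is identical by construction).
#'
#' @return list of class descriptors (name, sigma, mu, sd).
#' @export
defaultSimClasses <- function() {
  sigA <- matrix(c(1.0, 0.0, 0.5,
                   0.0, 0.3, 0.0,
                   0.5, 0.0, 1.0), 3, 3, byrow = TRUE)
  sigB <- matrix(c(1.0, 0.4, 0.5,
                   0.4, 0.3, 0.4,
                   0.5, 0.4, 1.0), 3, 3, byrow = TRUE)
  sigCD <- matrix(c(0.6, 0.0, 0.2,
                    0.0, 0.4, 0.0,
                    0.2, 0.0, 0.6), 3, 3, byrow = TRUE)
  list(
    list(name = "crop_a", sigma = sigA,
         mu = c(R = 0.12, G = 0.20, B = 0.10, NIR = 0.40),
         sd = rep(0.03, 4)),
    list(name = "crop_b", sigma = sigB,
         mu = c(R = 0.12, G = 0.20, B = 0.10, NIR = 0.40),
         sd = rep(0.03, 4)),
    list(name = "veg_c", sigma = sigCD,
         mu = c(R = 0.10, G = 0.25, B = 0.12, NIR = 0.45),
         sd = rep(0.03, 4)),
    list(name = "veg_d", sigma = sigCD,
         mu = c(R = 0.10, G = 0.16, B = 0.06, NIR = 0.45),
         sd = rep(0.03, 4)))
}

#' Simulation configuration
#'
#' @param classes list of class descriptors, each a list with \code{name},
#'   \code{sigma} (3x3 Hermitian PSD), \code{mu} (4 reflectance means in
#'   (0,1)) and \code{sd} (4 reflectance standard deviations).
#' @param looks number of looks L >= 1 (default 4).
#' @param size scene rows/cols (default 128 x 128).
#' @param fieldGrid number of field rows/cols in the rectangular mosaic;
#'   must divide \code{size} (default 8 x 8).
#' @param trainFieldFraction fraction of each class's fields reserved for
#'   training (default 0.25); training and testing pixels are disjoint by
#'   field.
#' @param maxTrainPixelsPerClass cap on training pixels per class
#'   (default 400).
#' @param seed RNG seed recorded in all outputs.
#' @return validated config list of class \code{simConfig}.
#' @export
simConfig <- function(classes = defaultSimClasses(), looks = 4,
                      size = c(128, 128), fieldGrid = c(8, 8),
                      trainFieldFraction = 0.25,
                      maxTrainPixelsPerClass = 400, seed = 42) {
  stopifnot(length(classes) >= 2, looks >= 1,
            length(size) == 2, length(fieldGrid) == 2)
  if (any(size %% fieldGrid != 0))
    stop("fieldGrid must divide the scene size")
  if (prod(fieldGrid) < 2 * length(classes))
    stop("scene too small: need at least 2 fields per class")
  for (cl in classes) {
    .hermitianFactor(cl$sigma + 0i)   # errors on non-PSD
    if (any(cl$mu <= 0 | cl$mu >= 1))
      stop("reflectance means must lie in (0,1)")
  }
  structure(list(classes = classes, looks = looks, size = as.integer(size),
                 fieldGrid = as.integer(fieldGrid),
                 trainFieldFraction = trainFieldFraction,
                 maxTrainPixelsPerClass = maxTrainPixelsPerClass,
                 seed = as.integer(seed)),
            class = "simConfig")
}

#' Generate a labeled PolSAR + optical scene
#'
#' Lays out a rectangular field mosaic with classes assigned cyclically,
#' draws each pixel's covariance matrix from its class's multi-look Wishart
#' model and its optical reflectances from truncated Gaussians in [0,1], and
#' splits training and testing pixels disjointly by field. Bit-identical for
#' a fixed config (including seed).
#'
#' @param cfg a \code{\link{simConfig}}.
#' @return list with \code{c3} (\code{C3Field}), \code{optical}
#'   (\code{OpticalBands}), \code{truth} (\code{ClassMap}), \code{train} and
#'   \code{test} (\code{TrainingSet}s) and \code{cfg}.
#' @export
generateScene <- function(cfg) {
  stopifnot(inherits(cfg, "simConfig"))
  set.seed(cfg$seed)
  nr <- cfg$size[1]; nc <- cfg$size[2]
  fr <- cfg$fieldGrid[1]; fc <- cfg$fieldGrid[2]
  fh <- nr %/% fr; fw <- nc %/% fc
  K <- length(cfg$classes)
  legend <- stats::setNames(vapply(cfg$classes, `[[`, "", "name"),
                            seq_len(K))

  fieldId <- outer(rep(seq_len(fr), each = fh),
                   (rep(seq_len(fc), each = fw) - 1) * fr, `+`)
  fieldClass <- (seq_len(fr * fc) - 1L) %% K + 1L
  labels <- matrix(fieldClass[fieldId], nr, nc)

  X <- matrix(0, nr * nc, 9)
  opt <- matrix(0, nr * nc, 4)
  for (k in seq_len(K)) {
    sel <- which(as.vector(labels) == k)
    X[sel, ] <- sampleWishartC3(cfg$classes[[k]]$sigma, cfg$looks,
                                length(sel))
    for (b in 1:4)
      opt[sel, b] <- .truncNorm01(length(sel), cfg$classes[[k]]$mu[b],
                                  cfg$classes[[k]]$sd[b])
  }
  c3 <- c3Field(array(X, c(nr, nc, 9), list(NULL, NULL, C3_PARAMS)),
                looks = cfg$looks)
  bands <- opticalBands(array(opt, c(nr, nc, 4),
                              list(NULL, NULL, c("R", "G", "B", "NIR"))))

  ## disjoint-by-field train/test split
  trainPx <- testPx <- list()
  for (k in seq_len(K)) {
    fields <- which(fieldClass == k)
    nTrain <- max(1L, ceiling(cfg$trainFieldFraction * length(fields)))
    trF <- sample(fields, nTrain)
    for (f in fields) {
      sel <- which(fieldId == f & labels == k, arr.ind = TRUE)
      df <- data.frame(row = sel[, 1], col = sel[, 2], classId = k,
                       plotId = f)
      if (f %in% trF) trainPx[[length(trainPx) + 1L]] <- df
      else testPx[[length(testPx) + 1L]] <- df
    }
  }
  trainDf <- do.call(rbind, trainPx)
  ## per-class cap, deterministic subsample
  capped <- lapply(split(trainDf, trainDf$classId), function(df) {
    if (nrow(df) > cfg$maxTrainPixelsPerClass)
      df[sample(nrow(df), cfg$maxTrainPixelsPerClass), ]
    else df
  })
  trainDf <- do.call(rbind, capped)
  rownames(trainDf) <- NULL
  testDf <- do.call(rbind, testPx)
  rownames(testDf) <- NULL

  list(c3 = c3, optical = bands,
       truth = classMap(labels, legend,
                        provenance = list(seed = cfg$seed, simulated = TRUE)),
       train = trainingSet(trainDf, legend),
       test = trainingSet(testDf, legend),
       cfg = cfg)
}
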