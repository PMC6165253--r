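#' Normalized difference vegetation index
#'
#' NDVI = (NIR - R) / (NIR + R), in [-1, 1]. Pixels with NIR + R == 0 are
#' masked rather than propagated as NaN.
#'
#' @param red,nir co-registered reflectance matrices, or an
#'   \code{\linkS4class{OpticalBands}} in \code{red} (bands "R" and "NIR").
#' @return list with \code{values} (matrix, NA where masked) and \code{mask}.
#' @export
ndvi <- function(red, nir = NULL) {
  if (is(red, "OpticalBands")) {
    ob <- red
    red <- layerData(ob, "R"); nir <- layerData(ob, "NIR")
    mask0 <- ob@mask
  } else mask0 <- matrix(TRUE, nrow(red), ncol(red))
  if (!identical(dim(red), dim(nir)))
    stop("red and nir must share one grid")
  s <- nir + red
  ok <- mask0 & is.finite(s) & s != 0
  v <- matrix(NA_real_, nrow(red), ncol(red))
  v[ok] <- (nir[ok] - red[ok]) / s[ok]
  list(values = v, mask = ok)
}

## windowed box sum with symmetric (reflection) padding, via integral image
.boxSum <- function(m, half) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(pmin(half:1, nr), 1:nr, nr + 1 - pmin(1:half, nr))
  ci <- c(pmin(half:1, nc), 1:nc, nc + 1 - pmin(1:half, nc))
  p <- m[ri, ci, drop = FALSE]
  cs <- apply(apply(p, 2, cumsum), 1, cumsum)   # transposed integral image
  cs <- t(cs)
  cs <- rbind(0, cbind(0, cs))
  w <- 2 * half + 1
  i0 <- 1:nr; j0 <- 1:nc
  cs[i0 + w, j0 + w, drop = FALSE] - cs[i0, j0 + w, drop = FALSE] -
    cs[i0 + w, j0, drop = FALSE] + cs[i0, j0, drop = FALSE]
}

#' Sliding-window information entropy texture
#'
#' Per-pixel Shannon entropy, in bits, of the gray-level histogram inside a
#' centered square window. Gray levels are \code{bins} equal-width bins over
#' the band's global valid min-max range; window edges use symmetric
#' reflection padding. The result lies in [0, log2(bins)].
#'
#' @param band numeric matrix.
#' @param window odd window side length >= 3 (default 7).
#' @param bins number of gray levels >= 2 (default 32).
#' @param mask optional logical validity matrix (used for the global range).
#' @return list with \code{values} (matrix) and \code{mask}.
#' @export
entropyTexture <- function(band, window = 7, bins = 32, mask = NULL) {
  stopifnot(window >= 3, window %% 2 == 1, bins >= 2)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(band), ncol(band))
  vals <- band[mask & is.finite(band)]
  rng <- range(vals)
  if (diff(rng) == 0) {
    warning("constant band: entropy is 0 everywhere")
    return(list(values = matrix(0, nrow(band), ncol(band)), mask = mask))
  }
  q <- floor((band - rng[1]) / diff(rng) * bins) + 1L
  q[q > bins] <- bins
  q[q < 1L] <- 1L
  q[!is.finite(band)] <- 1L
  half <- (window - 1L) / 2L
  total <- window^2
  H <- matrix(0, nrow(band), ncol(band))
  for (b in seq_len(bins)) {
    cnt <- .boxSum((q == b) * 1, half)
    p <- cnt / total
    nz <- p > 0
    H[nz] <- H[nz] - p[nz] * log2(p[nz])
  }
  list(values = H, mask = mask)
}

## PCA over valid pixels: rows = observations, cols = variables.
## Component sign is fixed so the largest-magnitude loading is positive.
## Returns the smallest leading set reaching varThreshold cumulative
## explained variance.
.pcaReduce <- function(X, varThreshold, center = TRUE, scale. = FALSE) {
  keepVar <- apply(X, 2, stats::var) > 0
  if (!all(keepVar)) {
    warning("dropping ", sum(!keepVar), " zero-variance variable(s) from PCA")
    X <- X[, keepVar, drop = FALSE]
  }
  if (ncol(X) < 1) stop("PCA needs at least one variable with nonzero variance")
  pc <- stats::prcomp(X, center = center, scale. = scale.)
  ev <- pc$sdev^2
  evf <- ev / sum(ev)
  k <- which(cumsum(evf) >= varThreshold - 1e-12)[1]
  if (is.na(k)) k <- length(evf)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    l <- pc$rotation[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, numeric(1))
  pc$rotation <- sweep(pc$rotation, 2, flip, "*")
  pc$x <- sweep(pc$x, 2, flip, "*")
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       loadings = pc$rotation,
       explained = evf,
       kept = k,
       center = pc$center, scale = pc$scale,
       droppedVars = which(!keepVar))
}

#' PCA reduction of optical bands
#'
#' Principal component analysis over the valid pixels (observations) of the
#' mean-centered reflectance bands (variables). Returns the smallest leading
#' component set whose cumulative explained-variance fraction reaches
#' \code{varThreshold}, as feature layers Opband_pca1, Opband_pca2, ...
#' Component sign is fixed so each component's largest-magnitude loading is
#' positive. Bands are centered but not rescaled (shared reflectance units);
#' set \code{standardize = TRUE} to scale to unit variance.
#'
#' @param bands an \code{\linkS4class{OpticalBands}}.
#' @param varThreshold cumulative explained-variance target (default 0.99).
#' @param standardize scale variables to unit variance before PCA.
#' @return a \code{\linkS4class{FeatureStack}} with attributes available via
#'   \code{pcaInfo}: loadings, explained-variance fractions, kept count.
#' @export
bandPCA <- function(bands, varThreshold = 0.99, standardize = FALSE) {
  stopifnot(is(bands, "OpticalBands"))
  d <- dim(bands@data)
  X <- matrix(bands@data, d[1] * d[2], d[3])
  ok <- as.vector(bands@mask) & rowSums(!is.finite(X)) == 0
  fit <- .pcaReduce(X[ok, , drop = FALSE], varThreshold, center = TRUE,
                    scale. = standardize)
  arr <- array(NA_real_, c(d[1], d[2], fit$kept),
               dimnames = list(NULL, NULL, paste0("Opband_pca", seq_len(fit$kept))))
  for (j in seq_len(fit$kept)) {
    pl <- rep(NA_real_, d[1] * d[2])
    pl[ok] <- fit$scores[, j]
    arr[, , j] <- pl
  }
  fs <- featureStack(arr, mask = matrix(ok, d[1], d[2]), provenance = "optical")
  attr(fs, "pca") <- fit[c("loadings", "explained", "kept", "center", "scale")]
  fs
}

#' PCA metadata of a PCA-derived feature stack
#' @param x a FeatureStack returned by \code{\link{bandPCA}} or
#'   \code{\link{sigmaPCA}}.
#' @return list with loadings, explained-variance fractions and kept count.
#' @export
pcaInfo <- function(x) attr(x, "pca")
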