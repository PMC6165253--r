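## Polarization-basis intensity transform.
##
## Each channel is the backscattered power DN_pq = <|q^T S p|^2> for a
## transmit Jones vector p and receive Jones vector q (backscatter alignment,
## reciprocal S). Expanding q^T S p as a linear form w . k in the
## lexicographic scattering vector k = (S_HH, sqrt2 S_HV, S_VV) gives
## DN = sum_ij w_i conj(w_j) C_ij, a real linear form in the 9 C3 parameters.
## Stacking the nine forms yields an invertible 9x9 real matrix.

.jonesStates <- function() {
  s2 <- sqrt(2)
  list(h   = c(1, 0),
       v   = c(0, 1),
       p45 = c(1, 1) / s2,
       m45 = c(1, -1) / s2,
       l   = c(1, 1i) / s2,
       r   = c(1, -1i) / s2)
}

## (transmit, receive) state pairs in canonical channel order
.channelPairs <- function() {
  list("hh"     = c("h", "h"),
       "vv"     = c("v", "v"),
       "+45+45" = c("p45", "p45"),
       "-45-45" = c("m45", "m45"),
       "ll"     = c("l", "l"),
       "rr"     = c("r", "r"),
       "h+45"   = c("p45", "h"),
       "hl"     = c("l", "h"),
       "+45l"   = c("l", "p45"))
}

## row of the forward matrix for one (p, q) state pair
.channelRow <- function(p, q) {
  ## q^T S p = q1 p1 S_HH + (q1 p2 + q2 p1) S_HV + q2 p2 S_VV
  w <- c(q[1] * p[1], (q[1] * p[2] + q[2] * p[1]) / sqrt(2), q[2] * p[2])
  row <- numeric(9)
  row[1:3] <- Mod(w)^2
  off <- list(c(1, 2), c(1, 3), c(2, 3))
  for (k in 1:3) {
    z <- w[off[[k]][1]] * Conj(w[off[[k]][2]])
    row[2 + 2 * k] <- 2 * Re(z)      # coefficient on Re C_ij
    row[3 + 2 * k] <- -2 * Im(z)     # coefficient on Im C_ij
  }
  row
}

#' Build the polarization-basis transform
#'
#' Constructs the forward 9x9 matrix M mapping the nine real C3 parameters to
#' the nine channel intensities (linear h/v, +-45 linear, left/right circular
#' transmit/receive combinations), and its inverse B, analytically from the
#' Jones vectors h=(1,0), v=(0,1), +45=(1,1)/sqrt2, -45=(1,-1)/sqrt2,
#' l=(1,i)/sqrt2, r=(1,-i)/sqrt2. The physical radiometric prefactor is kept
#' as a single global scale constant (default 1): it cancels in dB
#' differences, PCA, min-max normalization and every classifier downstream.
#'
#' @param scale global scale constant multiplying all intensities.
#' @return a \code{\linkS4class{BasisTransform}}.
#' @examples
#' bt <- buildBasisTransform()
#' range(bt@M %*% bt@B - diag(9))   # identity to machine precision
#' @export
buildBasisTransform <- function(scale = 1) {
  states <- .jonesStates()
  pairs <- .channelPairs()
  M <- t(vapply(pairs, function(pq) {
    .channelRow(states[[pq[1]]], states[[pq[2]]])
  }, numeric(9)))
  dimnames(M) <- list(POL_CHANNELS, C3_PARAMS)
  M <- M * scale
  B <- solve(M)
  stopifnot(max(abs(M %*% B - diag(9))) < 1e-10)
  new("BasisTransform", M = M, B = B, scale = scale)
}

#' Transform a covariance field to the 9-channel intensity vector
#'
#' Applies the forward basis transform per pixel: P = M c, with c the pixel's
#' 9-parameter vector. For positive semidefinite input all channels are
#' non-negative; values below \code{-1e-9 * span} trigger a warning count and
#' everything negative is clipped to zero.
#'
#' @param c3 a \code{\linkS4class{C3Field}}.
#' @param transform optional precomputed \code{BasisTransform}.
#' @return a \code{\linkS4class{PolIntensity}}.
#' @export
c3ToIntensity <- function(c3, transform = buildBasisTransform()) {
  stopifnot(is(c3, "C3Field"), is(transform, "BasisTransform"))
  d <- dim(c3@data)
  X <- matrix(c3@data, d[1] * d[2], 9)          # pixels x params
  P <- X %*% t(transform@M)                     # pixels x channels
  sp <- spanPower(c3)
  bad <- P < -1e-9 * pmax(as.vector(sp), 1e-30)
  nbad <- sum(bad & rep(c3@mask, 9))
  if (nbad > 0)
    warning(nbad, " channel value(s) below -1e-9*span clipped to 0 ",
            "(input not positive semidefinite?)")
  P[P < 0] <- 0
  arr <- array(P, dim = c(d[1], d[2], 9),
               dimnames = list(NULL, NULL, POL_CHANNELS))
  new("PolIntensity", data = arr, mask = c3@mask, scale = transform@scale)
}

#' Convert channel intensities to decibels
#'
#' Elementwise \code{10*log10(P)}; non-positive intensities are assigned the
#' documented floor so downstream normalization sees finite values.
#'
#' @param p a \code{\linkS4class{PolIntensity}}.
#' @param floorDb dB value for P <= 0 (default -50).
#' @return a \code{\linkS4class{SigmaDb}}.
#' @export
intensityToDb <- function(p, floorDb = -50) {
  stopifnot(is(p, "PolIntensity"))
  x <- p@data
  pos <- x > 0
  out <- array(floorDb, dim = dim(x), dimnames = dimnames(x))
  out[pos] <- 10 * log10(x[pos])
  new("SigmaDb", data = out, mask = p@mask, floorDb = floorDb)
}

## pixels x 9 parameter matrix -> per-pixel 3x3 complex matrices (list use
## is avoided; helper for code that needs explicit matrices)
.paramsToMatrix <- function(v) {
  matrix(c(v[1] + 0i,        v[4] + 1i * v[5],  v[6] + 1i * v[7],
           v[4] - 1i * v[5], v[2] + 0i,         v[8] + 1i * v[9],
           v[6] - 1i * v[7], v[8] - 1i * v[9],  v[3] + 0i),
         3, 3, byrow = TRUE)
}

## determinant of a 3x3 complex matrix (base det() is real-only)
.cdet3 <- function(S) {
  S[1, 1] * (S[2, 2] * S[3, 3] - S[2, 3] * S[3, 2]) -
    S[1, 2] * (S[2, 1] * S[3, 3] - S[2, 3] * S[3, 1]) +
    S[1, 3] * (S[2, 1] * S[3, 2] - S[2, 2] * S[3, 1])
}

.matrixToParams <- function(S) {
  c(Re(S[1, 1]), Re(S[2, 2]), Re(S[3, 3]),
    Re(S[1, 2]), Im(S[1, 2]), Re(S[1, 3]), Im(S[1, 3]),
    Re(S[2, 3]), Im(S[2, 3]))
}
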