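#' Total backscattered power (span)
#'
#' Span = <|S_HH|^2> + 2<|S_HV|^2> + <|S_VV|^2>, the trace of the
#' lexicographic covariance matrix.
#'
#' @param c3 a \code{\linkS4class{C3Field}}.
#' @return numeric matrix of per-pixel span.
#' @export
spanPower <- function(c3) {
  stopifnot(is(c3, "C3Field"))
  d <- dim(c3@data)
  matrix(c3@data[, , "C11"] + c3@data[, , "C22"] + c3@data[, , "C33"],
         d[1], d[2])
}

#' Radar vegetation index
#'
#' RVI = 8 <|S_HV|^2> / (<|S_HH|^2> + <|S_VV|^2> + 2 <|S_HV|^2>), in [0, 4]:
#' 0 for depolarization-free targets, 1 for a random dipole cloud, 4 in the
#' pure cross-pol limit. Zero-span pixels are masked rather than propagated
#' as NaN.
#'
#' @param c3 a \code{\linkS4class{C3Field}}.
#' @return list with \code{values} (matrix, NA where masked) and \code{mask}.
#' @export
rvi <- function(c3) {
  stopifnot(is(c3, "C3Field"))
  sp <- spanPower(c3)
  ok <- c3@mask & sp > 0
  v <- matrix(NA_real_, nrow(sp), ncol(sp))
  ## C22 = 2<|S_HV|^2>, so 8<|S_HV|^2> = 4*C22
  c22 <- matrix(c3@data[, , "C22"], nrow(sp), ncol(sp))
  v[ok] <- 4 * c22[ok] / sp[ok]
  list(values = v, mask = ok)
}

## per-pixel PSD test via leading principal minors with relative tolerance
.psdMask <- function(X, tol = 1e-9) {
  C11 <- X[, 1]; C22 <- X[, 2]; C33 <- X[, 3]
  C12 <- complex(real = X[, 4], imaginary = X[, 5])
  C13 <- complex(real = X[, 6], imaginary = X[, 7])
  C23 <- complex(real = X[, 8], imaginary = X[, 9])
  s <- pmax(C11 + C22 + C33, 1e-30)
  m2 <- C11 * C22 - Mod(C12)^2
  det3 <- Re(C11 * (C22 * C33 - Mod(C23)^2) -
             C12 * (Conj(C12) * C33 - C23 * Conj(C13)) +
             C13 * (Conj(C12) * Conj(C23) - C22 * Conj(C13)))
  C11 >= -tol * s & C22 >= -tol * s & C33 >= -tol * s &
    m2 >= -tol * s^2 & det3 >= -tol * s^3
}

#' Yamaguchi four-component decomposition
#'
#' Decomposes each pixel's covariance matrix into surface (Ps), double-bounce
#' (Pd), volume (Pv) and helix (Pc) powers following the four-component
#' scheme with helix extraction, three-branch volume model selection on the
#' 10 log10(<|S_VV|^2>/<|S_HH|^2>) ratio with +-2 dB thresholds, and the
#' surface/double-bounce split through the alpha/beta system. Helix power is
#' capped at 2<|S_HV|^2>; negative component powers are clipped to zero with
#' the deficit reassigned so that Ps+Pd+Pv+Pc equals the span exactly on
#' every valid pixel. Non-PSD pixels are masked out and counted.
#'
#' @param c3 a \code{\linkS4class{C3Field}}.
#' @return a \code{\linkS4class{YamaguchiPowers}}.
#' @export
yamaguchiDecompose <- function(c3) {
  stopifnot(is(c3, "C3Field"))
  d <- dim(c3@data)
  X <- matrix(c3@data, d[1] * d[2], 9)
  colnames(X) <- C3_PARAMS
  psd <- .psdMask(X)
  ok <- as.vector(c3@mask) & psd
  nNonPsd <- sum(as.vector(c3@mask) & !psd)

  n <- nrow(X)
  Ps <- Pd <- Pv <- Pc <- numeric(n)
  sp <- X[, "C11"] + X[, "C22"] + X[, "C33"]

  i <- which(ok)
  if (length(i)) {
    C11 <- X[i, "C11"]; C22 <- X[i, "C22"]; C33 <- X[i, "C33"]
    ReC13 <- X[i, "ReC13"]; ImC13 <- X[i, "ImC13"]
    span <- sp[i]

    ## helix: Pc = 2|Im(<S_HH S_HV*> + <S_HV S_VV*>)| = sqrt2 |ImC12 + ImC23|,
    ## capped at the total cross-pol power 2<|S_HV|^2> = C22
    pc <- pmin(sqrt(2) * abs(X[i, "ImC12"] + X[i, "ImC23"]), C22)
    pc <- pmin(pc, span)

    ## volume branch on the VV/HH ratio (+-2 dB); model matrices are
    ## trace-normalized so Pv = fv
    ratio <- 10 * (log10(pmax(C33, 1e-300)) - log10(pmax(C11, 1e-300)))
    v11 <- ifelse(ratio < -2, 8 / 15, ifelse(ratio > 2, 3 / 15, 3 / 8))
    v22 <- ifelse(abs(ratio) <= 2, 1 / 4, 4 / 15)
    v33 <- ifelse(ratio < -2, 3 / 15, ifelse(ratio > 2, 8 / 15, 3 / 8))
    v13 <- ifelse(abs(ratio) <= 2, 1 / 8, 2 / 15)

    fv <- pmax((C22 - pc / 2) / v22, 0)
    pv <- pmin(fv, pmax(span - pc, 0))
    fv <- pv

    ## residual surface + double-bounce power; A + B = span - pv - pc exactly
    A <- C11 - fv * v11 - pc / 4
    B <- C33 - fv * v33 - pc / 4
    Cr <- ReC13 - fv * v13 + pc / 4
    Ci <- ImC13
    TP <- pmax(span - pv - pc, 0)

    ps <- numeric(length(i))
    disc <- A * B - (Cr^2 + Ci^2)
    surf <- Cr >= 0
    ## surface dominant: alpha = -1, Pd = 2 fd
    denS <- A + B + 2 * Cr
    fd <- ifelse(surf & denS > 0, disc / denS, 0)
    ## double-bounce dominant: beta = 1, Ps = 2 fs
    denD <- A + B - 2 * Cr
    fs <- ifelse(!surf & denD > 0, disc / denD, 0)
    ps <- ifelse(surf, TP - 2 * fd, 2 * fs)
    ps <- pmin(pmax(ps, 0), TP)
    pd <- TP - ps                     # conservation exact by construction

    Ps[i] <- ps; Pd[i] <- pd; Pv[i] <- pv; Pc[i] <- pc
  }

  shape <- function(v) matrix(v, d[1], d[2])
  new("YamaguchiPowers",
      Ps = shape(Ps), Pd = shape(Pd), Pv = shape(Pv), Pc = shape(Pc),
      span = shape(sp), mask = matrix(ok, d[1], d[2]),
      nNonPsd = as.integer(nNonPsd))
}

#' Convert a Pauli-basis coherency field to the lexicographic basis
#'
#' Applies the fixed unitary similarity C3 = U^H T3 U with the standard
#' Pauli-to-lexicographic change of basis; the trace (total power) is
#' preserved to 1e-10.
#'
#' @param t3data rows x cols x 9 array of T3 parameter planes in the same
#'   plane order as \code{\link{c3Parameters}} (diagonals first, then
#'   Re/Im of the upper off-diagonals T12, T13, T23).
#' @param looks equivalent number of looks.
#' @param mask optional validity matrix.
#' @return a \code{\linkS4class{C3Field}}.
#' @export
t3ToC3 <- function(t3data, looks = 1, mask = NULL) {
  d <- dim(t3data)
  stopifnot(length(d) == 3L, d[3] == 9L)
  s2 <- sqrt(2)
  ## k_lex = U k_pauli with k_pauli = (HH+VV, HH-VV, 2HV)/sqrt2
  U <- matrix(c(1 / s2,  1 / s2, 0,
                0,       0,      1,
                1 / s2, -1 / s2, 0), 3, 3, byrow = TRUE)
  X <- matrix(t3data, d[1] * d[2], 9)
  out <- matrix(0, d[1] * d[2], 9)
  ## C = U T U^H is real-linear in the T parameters: precompute the 9x9 map
  ## by pushing each unit parameter through the similarity
  map <- matrix(0, 9, 9)
  for (k in 1:9) {
    e <- numeric(9); e[k] <- 1
    Tm <- .paramsToMatrix(e)
    map[, k] <- .matrixToParams(U %*% Tm %*% Conj(t(U)))
  }
  out <- X %*% t(map)
  arr <- array(out, dim = d, dimnames = list(NULL, NULL, C3_PARAMS))
  c3Field(arr, looks = looks, mask = mask)
}
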