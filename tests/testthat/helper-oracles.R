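## Shared fixtures and independent oracles, built in code.

## Frobenius norm that keeps the imaginary parts (base norm() is real-only)
frobNorm <- function(X) sqrt(sum(Mod(X)^2))

## random Hermitian PSD 3x3 as a 9-parameter vector (canonical plane order)
randomPsdParams <- function() {
  A <- matrix(complex(real = rnorm(9), imaginary = rnorm(9)), 3, 3)
  C <- A %*% Conj(t(A))
  c(Re(C[1, 1]), Re(C[2, 2]), Re(C[3, 3]),
    Re(C[1, 2]), Im(C[1, 2]), Re(C[1, 3]), Im(C[1, 3]),
    Re(C[2, 3]), Im(C[2, 3]))
}

paramsToC3Matrix <- function(v) {
  matrix(c(v[1] + 0i,        v[4] + 1i * v[5],  v[6] + 1i * v[7],
           v[4] - 1i * v[5], v[2] + 0i,         v[8] + 1i * v[9],
           v[6] - 1i * v[7], v[8] - 1i * v[9],  v[3] + 0i),
         3, 3, byrow = TRUE)
}

## single- or multi-pixel C3Field from parameter rows (pixels x 9)
rowsToField <- function(rows, looks = 1) {
  arr <- array(0, c(1, nrow(rows), 9))
  arr[1, , ] <- rows
  c3Field(arr, looks = looks)
}

pixelField <- function(..., looks = 1) {
  rowsToField(rbind(...), looks = looks)
}

## C3 parameter vector of a deterministic Sinclair matrix (reciprocal)
sinclairParams <- function(shh, shv, svv) {
  k <- c(shh, sqrt(2) * shv, svv)
  C <- outer(k, Conj(k))
  c(Re(C[1, 1]), Re(C[2, 2]), Re(C[3, 3]),
    Re(C[1, 2]), Im(C[1, 2]), Re(C[1, 3]), Im(C[1, 3]),
    Re(C[2, 3]), Im(C[2, 3]))
}

## Brute-force channel-intensity oracle: decompose the covariance into its
## eigen-scatterers and evaluate |q^T S p|^2 on the explicit Sinclair matrix
## of each, for every transmit/receive state pair. Independent of the
## package's linear-form construction.
oracleIntensities <- function(params) {
  states <- list(h = c(1, 0), v = c(0, 1),
                 p45 = c(1, 1) / sqrt(2), m45 = c(1, -1) / sqrt(2),
                 l = c(1, 1i) / sqrt(2), r = c(1, -1i) / sqrt(2))
  pairs <- list(c("h", "h"), c("v", "v"), c("p45", "p45"), c("m45", "m45"),
                c("l", "l"), c("r", "r"), c("p45", "h"), c("l", "h"),
                c("l", "p45"))
  C <- paramsToC3Matrix(params)
  e <- eigen(C)
  vapply(pairs, function(pq) {
    p <- states[[pq[1]]]; q <- states[[pq[2]]]
    sum(vapply(1:3, function(i) {
      lam <- Re(e$values[i])
      if (lam < 0) lam <- 0
      k <- e$vectors[, i]
      S <- matrix(c(k[1], k[2] / sqrt(2), k[2] / sqrt(2), k[3]), 2, 2)
      lam * Mod(sum(q * (S %*% p)))^2
    }, numeric(1)))
  }, numeric(1))
}

## Straight-line scalar reference of the four-component decomposition,
## written directly from the published branching on one complex matrix.
oracleYamaguchi <- function(params) {
  C <- paramsToC3Matrix(params)
  hh2 <- Re(C[1, 1]); hv2 <- Re(C[2, 2]) / 2; vv2 <- Re(C[3, 3])
  span <- hh2 + 2 * hv2 + vv2
  hhhv <- C[1, 2] / sqrt(2); hvvv <- C[2, 3] / sqrt(2)
  pc <- min(2 * abs(Im(hhhv + hvvv)), 2 * hv2, span)
  ratio <- 10 * log10(vv2 / hh2)
  if (is.nan(ratio)) ratio <- 0
  if (ratio < -2)      { v <- c(8, 4, 3, 2) / 15 }
  else if (ratio > 2)  { v <- c(3, 4, 8, 2) / 15 }
  else                 { v <- c(3, 2, 3, 1) / 8 }
  fv <- max((2 * hv2 - pc / 2) / v[2], 0)
  pv <- min(fv, max(span - pc, 0))
  A <- hh2 - pv * v[1] - pc / 4
  B <- vv2 - pv * v[3] - pc / 4
  Cr <- C[1, 3] - pv * v[4] + pc / 4
  TP <- max(span - pv - pc, 0)
  disc <- A * B - Mod(Cr)^2
  if (TP <= 0) { ps <- 0 }
  else if (Re(Cr) >= 0) {
    den <- A + B + 2 * Re(Cr)
    fd <- if (den > 0) disc / den else 0
    ps <- TP - 2 * fd
  } else {
    den <- A + B - 2 * Re(Cr)
    fs <- if (den > 0) disc / den else 0
    ps <- 2 * fs
  }
  ps <- min(max(ps, 0), TP)
  c(Ps = ps, Pd = TP - ps, Pv = pv, Pc = pc, span = span)
}

## small labeled scene for classifier tests
tinyScene <- function(seed = 7, size = c(64, 64), looks = 4) {
  generateScene(simConfig(size = size, fieldGrid = c(4, 4), looks = looks,
                          seed = seed))
}
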