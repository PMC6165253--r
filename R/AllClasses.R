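#' @import methods
NULL

## Canonical plane order for the 9 real parameters of a lexicographic 3x3
## Hermitian covariance matrix C3, scattering vector k = (S_HH, sqrt2*S_HV, S_VV).
C3_PARAMS <- c("C11", "C22", "C33",
               "ReC12", "ImC12", "ReC13", "ImC13", "ReC23", "ImC23")

## Fixed channel order of the polarization-basis intensity vector:
## transmit/receive pairs on the linear h/v, +-45 deg linear, and left/right
## circular bases.
POL_CHANNELS <- c("hh", "vv", "+45+45", "-45-45", "ll", "rr",
                  "h+45", "hl", "+45l")

#' Multi-look polarimetric covariance field
#'
#' Per-pixel 3x3 Hermitian covariance matrices in the lexicographic basis
#' (S_HH, sqrt(2) S_HV, S_VV), stored as nine real parameter planes in the
#' order \code{C11, C22, C33, ReC12, ImC12, ReC13, ImC13, ReC23, ImC23}.
#' Hermitian symmetry is implied by the storage; diagonal planes must be
#' non-negative (values above -1e-12 are clipped to zero on construction).
#'
#' @slot data numeric array \code{rows x cols x 9}, third dimension named by
#'   parameter.
#' @slot looks equivalent number of looks (>= 1).
#' @slot mask logical matrix of per-pixel validity.
#' @slot pixelSpacing numeric length-2 (row, col) spacing metadata.
#' @exportClass C3Field
setClass("C3Field",
         representation(data = "array", looks = "numeric", mask = "matrix",
                        pixelSpacing = "numeric"))

setValidity("C3Field", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L || d[3] != 9L)
    return("data must be a rows x cols x 9 array")
  if (!identical(dimnames(object@data)[[3]], C3_PARAMS))
    return("third dimension must be named by the 9 C3 parameters")
  if (!is.logical(object@mask) || !identical(dim(object@mask), d[1:2]))
    return("mask must be a logical matrix matching the grid")
  if (length(object@looks) != 1L || object@looks < 1)
    return("looks must be a single value >= 1")
  diag3 <- object@data[, , 1:3, drop = FALSE]
  v <- diag3[rep(object@mask, 3)]
  if (any(v < -1e-12, na.rm = TRUE))
    return("diagonal C3 entries must be >= -1e-12 on valid pixels")
  TRUE
})

#' Construct a C3Field from parameter planes
#'
#' @param data rows x cols x 9 array in the canonical parameter order
#'   (see \code{\link{c3Parameters}}).
#' @param looks equivalent number of looks.
#' @param mask optional logical validity matrix; default all valid.
#' @param pixelSpacing numeric length-2 spacing metadata.
#' @return a \code{C3Field}.
#' @export
c3Field <- function(data, looks = 1, mask = NULL, pixelSpacing = c(1, 1)) {
  d <- dim(data)
  stopifnot(length(d) == 3L, d[3] == 9L)
  dimnames(data)[[3]] <- C3_PARAMS
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  ## clip tiny negative diagonals arising from round-off
  for (k in 1:3) {
    pl <- data[, , k]
    pl[pl > -1e-12 & pl < 0] <- 0
    data[, , k] <- pl
  }
  new("C3Field", data = data, looks = as.numeric(looks), mask = mask,
      pixelSpacing = as.numeric(pixelSpacing))
}

#' Canonical C3 parameter order
#' @return character vector of the nine plane names.
#' @export
c3Parameters <- function() C3_PARAMS

#' Polarization channel order of the intensity vector
#' @return character vector of the nine channel names.
#' @export
polChannels <- function() POL_CHANNELS

#' Nine-channel polarization-basis intensity field
#'
#' Backscatter intensities on the nine transmit/receive polarization states
#' (linear h/v, +-45 degree linear, left/right circular), the image of the C3
#' parameter vector under the forward basis transform. All channels are
#' non-negative for positive semidefinite input.
#'
#' @slot data numeric array rows x cols x 9, channels named.
#' @slot mask logical validity matrix.
#' @slot scale global scale constant applied to all channels.
#' @exportClass PolIntensity
setClass("PolIntensity",
         representation(data = "array", mask = "matrix", scale = "numeric"))

setValidity("PolIntensity", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L || d[3] != 9L) return("data must be rows x cols x 9")
  if (!identical(dimnames(object@data)[[3]], POL_CHANNELS))
    return("channels must be named in the canonical order")
  if (length(object@scale) != 1L || object@scale <= 0)
    return("scale must be a positive scalar")
  TRUE
})

#' Nine-channel backscatter field in decibels
#'
#' @slot data numeric array rows x cols x 9 of dB values.
#' @slot mask logical validity matrix.
#' @slot floorDb dB value substituted where the linear intensity was <= 0.
#' @exportClass SigmaDb
setClass("SigmaDb",
         representation(data = "array", mask = "matrix", floorDb = "numeric"))

#' Polarization basis transform
#'
#' Real 9x9 matrix M mapping the nine C3 parameters to the nine channel
#' intensities, and its inverse B (intensities back to C3 parameters).
#'
#' @slot M forward 9x9 matrix (parameters -> intensities).
#' @slot B inverse 9x9 matrix (intensities -> parameters).
#' @slot scale global scale constant folded out of M (default 1).
#' @exportClass BasisTransform
setClass("BasisTransform",
         representation(M = "matrix", B = "matrix", scale = "numeric"))

setValidity("BasisTransform", function(object) {
  if (!identical(dim(object@M), c(9L, 9L))) return("M must be 9x9")
  if (max(abs(object@M %*% object@B - diag(9))) > 1e-10)
    return("B must invert M to 1e-10")
  TRUE
})

#' Yamaguchi four-component powers
#'
#' Per-pixel surface (Ps), double-bounce (Pd), volume (Pv) and helix (Pc)
#' scattering powers; conservation Ps+Pd+Pv+Pc = span holds exactly on every
#' valid pixel.
#'
#' @slot Ps,Pd,Pv,Pc numeric power matrices.
#' @slot span numeric total-power matrix.
#' @slot mask logical validity matrix (non-PSD pixels masked).
#' @slot nNonPsd count of pixels masked as non positive semidefinite.
#' @exportClass YamaguchiPowers
setClass("YamaguchiPowers",
         representation(Ps = "matrix", Pd = "matrix", Pv = "matrix",
                        Pc = "matrix", span = "matrix", mask = "matrix",
                        nNonPsd = "integer"))

setValidity("YamaguchiPowers", function(object) {
  m <- object@mask
  for (nm in c("Ps", "Pd", "Pv", "Pc")) {
    v <- slot(object, nm)[m]
    if (any(v < 0, na.rm = TRUE)) return(paste(nm, "must be >= 0"))
  }
  tot <- (object@Ps + object@Pd + object@Pv + object@Pc)[m]
  sp <- object@span[m]
  if (any(abs(tot - sp) > 1e-6 * pmax(sp, 1e-30)))
    return("power conservation violated beyond 1e-6 relative")
  TRUE
})

#' Co-registered optical reflectance bands
#'
#' @slot data numeric array rows x cols x nbands, bands named (R, G, B, NIR).
#' @slot mask logical validity matrix.
#' @exportClass OpticalBands
setClass("OpticalBands",
         representation(data = "array", mask = "matrix"))

setValidity("OpticalBands", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L) return("data must be rows x cols x bands")
  if (is.null(dimnames(object@data)[[3]])) return("bands must be named")
  if (!identical(dim(object@mask), d[1:2])) return("mask/grid mismatch")
  TRUE
})

#' Construct an OpticalBands object
#' @param data rows x cols x bands array with named bands.
#' @param mask optional logical validity matrix.
#' @return an \code{OpticalBands}.
#' @export
opticalBands <- function(data, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, dim(data)[1], dim(data)[2])
  new("OpticalBands", data = data, mask = mask)
}

#' Named stack of co-registered feature rasters
#'
#' @slot data numeric array rows x cols x nlayers, layers named.
#' @slot mask joint logical validity matrix.
#' @slot provenance character per-layer source tag ("sar" or "optical").
#' @slot normalization list of per-layer (min, max) used for min-max scaling,
#'   or empty if the stack is unnormalized.
#' @exportClass FeatureStack
setClass("FeatureStack",
         representation(data = "array", mask = "matrix",
                        provenance = "character", normalization = "list"))

setValidity("FeatureStack", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L) return("data must be rows x cols x layers")
  nms <- dimnames(object@data)[[3]]
  if (is.null(nms) || anyDuplicated(nms)) return("layers must be uniquely named")
  if (length(object@provenance) != d[3]) return("provenance length mismatch")
  if (!identical(dim(object@mask), d[1:2])) return("mask/grid mismatch")
  if (length(object@normalization)) {
    v <- object@data[rep(object@mask, d[3])]
    if (any(v < -1e-9 | v > 1 + 1e-9, na.rm = TRUE))
      return("normalized layers must lie in [0,1] on valid pixels")
  }
  TRUE
})

#' Construct a FeatureStack
#' @param data rows x cols x layers array with named layers (a plain named
#'   list of matrices is also accepted).
#' @param mask optional joint validity matrix.
#' @param provenance per-layer source tag, recycled if scalar.
#' @param normalization per-layer min/max list (empty for raw stacks).
#' @return a \code{FeatureStack}.
#' @export
featureStack <- function(data, mask = NULL, provenance = "sar",
                         normalization = list()) {
  if (is.list(data) && !is.array(data)) {
    nms <- names(data)
    data <- array(unlist(data, use.names = FALSE),
                  dim = c(dim(data[[1]]), length(data)),
                  dimnames = list(NULL, NULL, nms))
  }
  d <- dim(data)
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  provenance <- rep_len(provenance, d[3])
  new("FeatureStack", data = data, mask = mask, provenance = provenance,
      normalization = normalization)
}

#' Integer class-label raster
#'
#' @slot labels integer matrix; 0 encodes nodata.
#' @slot legend named character vector mapping class id to class name
#'   (names are the ids as strings).
#' @slot provenance list of free-form metadata (model, mode, config hash).
#' @exportClass ClassMap
setClass("ClassMap",
         representation(labels = "matrix", legend = "character",
                        provenance = "list"))

setValidity("ClassMap", function(object) {
  ids <- c(0L, as.integer(names(object@legend)))
  u <- unique(as.integer(object@labels))
  if (!all(u %in% ids)) return("labels must be legend ids or 0 (nodata)")
  TRUE
})

#' Construct a ClassMap
#' @param labels integer matrix (0 = nodata).
#' @param legend named character vector (names = ids).
#' @param provenance metadata list.
#' @return a \code{ClassMap}.
#' @export
classMap <- function(labels, legend, provenance = list()) {
  storage.mode(labels) <- "integer"
  labels[is.na(labels)] <- 0L
  new("ClassMap", labels = labels, legend = legend, provenance = provenance)
}

#' Per-class complex Wishart class model
#'
#' @slot sigma list of per-class 3x3 complex Hermitian mean covariances.
#' @slot counts integer training-pixel counts per class.
#' @slot epsilon diagonal regularization added where a class mean was singular.
#' @slot legend named character vector of class names.
#' @exportClass WishartModel
setClass("WishartModel",
         representation(sigma = "list", counts = "integer",
                        epsilon = "numeric", legend = "character"))

setValidity("WishartModel", function(object) {
  if (length(object@sigma) != length(object@legend))
    return("one covariance per legend class required")
  for (S in object@sigma) {
    if (!is.complex(S) && !is.numeric(S)) return("sigma entries must be matrices")
    if (!identical(dim(S), c(3L, 3L))) return("sigma entries must be 3x3")
    if (max(abs(S - Conj(t(S)))) > 1e-9 * max(abs(S), 1e-30))
      return("class covariances must be Hermitian")
  }
  TRUE
})

#' Confusion matrix with legend
#'
#' Rows are the classified class, columns the reference class.
#'
#' @slot counts K x K non-negative numeric matrix (integer-valued).
#' @slot legend named character vector of class names in row/column order.
#' @exportClass ConfusionMatrix
setClass("ConfusionMatrix",
         representation(counts = "matrix", legend = "character"))

setValidity("ConfusionMatrix", function(object) {
  cm <- object@counts
  if (nrow(cm) != ncol(cm)) return("counts must be square")
  if (nrow(cm) != length(object@legend)) return("legend/counts size mismatch")
  if (any(cm < 0)) return("counts must be non-negative")
  if (sum(cm) <= 0) return("total count must be positive")
  TRUE
})

#' Construct a ConfusionMatrix
#' @param counts square count matrix, rows = classified, cols = reference.
#' @param legend class names in row order; defaults to counts dimnames.
#' @return a \code{ConfusionMatrix}.
#' @export
confusionMatrix <- function(counts, legend = NULL) {
  counts <- as.matrix(counts)
  if (is.null(legend)) legend <- rownames(counts)
  if (is.null(names(legend))) names(legend) <- seq_along(legend)
  dimnames(counts) <- list(classified = legend, reference = legend)
  new("ConfusionMatrix", counts = counts, legend = legend)
}

## ---- accessors ----

#' @describeIn c3Field parameter-plane array accessor.
#' @param x a C3Field.
#' @export
c3Data <- function(x) x@data

#' @describeIn c3Field equivalent number of looks.
#' @export
looks <- function(x) x@looks

#' Validity mask of a raster object
#' @param x a C3Field, FeatureStack, OpticalBands, PolIntensity or SigmaDb.
#' @return logical matrix.
#' @export
validMask <- function(x) x@mask

#' Layer / band / channel data of a stack-like object
#' @param x a FeatureStack, OpticalBands, PolIntensity or SigmaDb.
#' @param layer optional layer name; if given, returns that matrix.
#' @return array, or matrix when \code{layer} is given.
#' @export
layerData <- function(x, layer = NULL) {
  if (is.null(layer)) return(x@data)
  nms <- dimnames(x@data)[[3]]
  if (!layer %in% nms) stop("no layer named '", layer, "'")
  d <- dim(x@data)
  matrix(x@data[, , match(layer, nms)], d[1], d[2])
}

#' Layer names of a stack-like object
#' @param x a FeatureStack, OpticalBands, PolIntensity or SigmaDb.
#' @export
layerNames <- function(x) dimnames(x@data)[[3]]

#' Class legend of a map, model or confusion matrix
#' @param x a ClassMap, WishartModel or ConfusionMatrix.
#' @export
classLegend <- function(x) x@legend

#' Label matrix of a ClassMap (0 = nodata)
#' @param x a ClassMap.
#' @export
classLabels <- function(x) x@labels

#' Counts of a ConfusionMatrix
#' @param x a ConfusionMatrix.
#' @export
confusionCountsOf <- function(x) x@counts

## ---- show methods ----

setMethod("show", "C3Field", function(object) {
  d <- dim(object@data)
  cat(sprintf("C3Field: %d x %d pixels, L = %g looks, %d valid (%.1f%%)\n",
              d[1], d[2], object@looks, sum(object@mask),
              100 * mean(object@mask)))
})

setMethod("show", "FeatureStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("FeatureStack: %d x %d pixels, %d layers%s\n", d[1], d[2], d[3],
              if (length(object@normalization)) " (normalized)" else ""))
  cat("  layers:", paste(dimnames(object@data)[[3]], collapse = ", "), "\n")
})

setMethod("show", "PolIntensity", function(object) {
  d <- dim(object@data)
  cat(sprintf("PolIntensity: %d x %d pixels, 9 channels, scale = %g\n",
              d[1], d[2], object@scale))
})

setMethod("show", "SigmaDb", function(object) {
  d <- dim(object@data)
  cat(sprintf("SigmaDb: %d x %d pixels, 9 channels, floor = %g dB\n",
              d[1], d[2], object@floorDb))
})

setMethod("show", "YamaguchiPowers", function(object) {
  cat(sprintf("YamaguchiPowers: %d x %d pixels, %d non-PSD masked\n",
              nrow(object@Ps), ncol(object@Ps), object@nNonPsd))
})

setMethod("show", "ClassMap", function(object) {
  tb <- table(factor(object@labels[object@labels != 0L],
                     levels = names(object@legend)))
  cat(sprintf("ClassMap: %d x %d pixels, %d classes, %d nodata\n",
              nrow(object@labels), ncol(object@labels), length(object@legend),
              sum(object@labels == 0L)))
  print(stats::setNames(as.integer(tb), object@legend))
})

setMethod("show", "WishartModel", function(object) {
  cat(sprintf("WishartModel: %d classes (%s), epsilon = %g\n",
              length(object@legend), paste(object@legend, collapse = ", "),
              object@epsilon))
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat("ConfusionMatrix (rows = classified, cols = reference):\n")
  print(object@counts)
})
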