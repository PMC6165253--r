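#' Min-max normalization of a feature stack
#'
#' Rescales each layer to [0, 1] over the valid pixels: (x - min)/(max - min).
#' In robust mode the 1st/99th percentiles replace min/max and values are
#' clipped into [0, 1]. Zero-range layers are set to 0 with a warning. The
#' constants used are recorded in the stack so they can be reapplied to a
#' prediction scene with \code{constants}.
#'
#' @param stack a \code{\linkS4class{FeatureStack}}.
#' @param robust use 1st/99th percentile bounds with clipping.
#' @param constants optional normalization constants from a previously
#'   normalized (training) stack, reused instead of recomputing.
#' @return a normalized \code{FeatureStack}.
#' @export
minmaxNormalize <- function(stack, robust = FALSE, constants = NULL) {
  stopifnot(is(stack, "FeatureStack"))
  d <- dim(stack@data)
  nms <- layerNames(stack)
  out <- stack@data
  norm <- list()
  for (j in seq_len(d[3])) {
    pl <- out[, , j]
    v <- pl[stack@mask & is.finite(pl)]
    if (!is.null(constants)) {
      lo <- constants[[nms[j]]][1]; hi <- constants[[nms[j]]][2]
      if (is.null(lo) || is.na(lo)) stop("no stored constants for layer ", nms[j])
    } else if (robust) {
      qs <- stats::quantile(v, c(0.01, 0.99), names = FALSE)
      lo <- qs[1]; hi <- qs[2]
    } else {
      lo <- min(v); hi <- max(v)
    }
    if (hi - lo <= 0) {
      warning("layer '", nms[j], "' has zero range; set to 0")
      pl[] <- 0
    } else {
      pl <- (pl - lo) / (hi - lo)
      pl <- pmin(pmax(pl, 0), 1)
    }
    out[, , j] <- pl
    norm[[nms[j]]] <- c(lo, hi)
  }
  new("FeatureStack", data = out, mask = stack@mask,
      provenance = stack@provenance, normalization = norm)
}

#' PCA reduction of the 9-channel dB backscatter vector
#'
#' Applies principal component analysis (same contract as
#' \code{\link{bandPCA}}) to the nine dB channels, producing feature layers
#' sigma_pca1, sigma_pca2, ... The default cumulative explained-variance
#' threshold is 0.98; the number of kept components is data-driven.
#'
#' @param sigma a \code{\linkS4class{SigmaDb}} (or, with
#'   \code{linear = TRUE} semantics handled by the caller, any 9-channel
#'   stack-like object with data and mask slots).
#' @param varThreshold cumulative explained-variance target (default 0.98).
#' @return a \code{\linkS4class{FeatureStack}} with \code{\link{pcaInfo}}.
#' @export
sigmaPCA <- function(sigma, varThreshold = 0.98) {
  d <- dim(sigma@data)
  X <- matrix(sigma@data, d[1] * d[2], d[3])
  ok <- as.vector(sigma@mask) & rowSums(!is.finite(X)) == 0
  if (sum(ok) < 2) stop("PCA needs at least 2 valid pixels")
  fit <- .pcaReduce(X[ok, , drop = FALSE], varThreshold)
  arr <- array(NA_real_, c(d[1], d[2], fit$kept),
               dimnames = list(NULL, NULL, paste0("sigma_pca", seq_len(fit$kept))))
  for (j in seq_len(fit$kept)) {
    pl <- rep(NA_real_, d[1] * d[2])
    pl[ok] <- fit$scores[, j]
    arr[, , j] <- pl
  }
  fs <- featureStack(arr, mask = matrix(ok, d[1], d[2]), provenance = "sar")
  attr(fs, "pca") <- fit[c("loadings", "explained", "kept", "center", "scale")]
  fs
}

#' Feature integration modes
#'
#' Named layer lists of the supported stacking modes: the full 11-layer
#' integration (7 SAR + 4 optical), the two reduced integrations
#' (\code{sar7_opt2}: SAR 7 + NDVI and H only; \code{sar5_opt4}: no
#' sigma-PCA layers + optical 4), and the two single-source modes used for
#' comparison.
#'
#' @return named list; each element has \code{sar} and \code{optical}
#'   character vectors of layer names.
#' @export
integrationModes <- function() {
  sar7 <- c("sigma_pca1", "sigma_pca2", "RVI", "Ps", "Pd", "Ph", "Pv")
  sar5 <- c("RVI", "Ps", "Pd", "Ph", "Pv")
  opt4 <- c("Opband_pca1", "Opband_pca2", "NDVI", "H")
  opt2 <- c("NDVI", "H")
  list(full         = list(sar = sar7, optical = opt4),
       sar7_opt2    = list(sar = sar7, optical = opt2),
       sar5_opt4    = list(sar = sar5, optical = opt4),
       sar_only     = list(sar = sar7, optical = character(0)),
       optical_only = list(sar = character(0), optical = opt4))
}

#' Assemble an integrated feature stack
#'
#' Selects the requested mode's layers from the SAR and optical feature
#' stacks, min-max normalizes them, and joins the masks conservatively (a
#' pixel invalid in any contributing layer is invalid in the stack).
#'
#' @param mode one of \code{names(integrationModes())}.
#' @param sarFeatures \code{FeatureStack} holding the SAR-side layers.
#' @param opticalFeatures \code{FeatureStack} holding the optical-side layers.
#' @param robust robust normalization flag, passed to
#'   \code{\link{minmaxNormalize}}.
#' @param constants optional stored normalization constants (training-scene
#'   statistics reused on a prediction scene).
#' @return a normalized \code{\linkS4class{FeatureStack}}.
#' @export
assembleFeatures <- function(mode, sarFeatures = NULL, opticalFeatures = NULL,
                             robust = FALSE, constants = NULL) {
  modes <- integrationModes()
  if (!mode %in% names(modes))
    stop("unknown integration mode '", mode, "'; use one of: ",
         paste(names(modes), collapse = ", "))
  want <- modes[[mode]]
  pick <- function(fs, lys, tag) {
    if (!length(lys)) return(NULL)
    if (is.null(fs)) stop("mode '", mode, "' needs ", tag, " features")
    missing <- setdiff(lys, layerNames(fs))
    if (length(missing))
      stop("mode '", mode, "' is missing ", tag, " layer(s): ",
           paste(missing, collapse = ", "))
    fs
  }
  sarFs <- pick(sarFeatures, want$sar, "sar")
  optFs <- pick(opticalFeatures, want$optical, "optical")

  grids <- lapply(Filter(Negate(is.null), list(sarFs, optFs)),
                  function(f) dim(f@data)[1:2])
  if (length(unique(grids)) != 1) stop("feature stacks are not co-registered")
  d <- grids[[1]]

  nms <- c(want$sar, want$optical)
  prov <- c(rep("sar", length(want$sar)), rep("optical", length(want$optical)))
  arr <- array(NA_real_, c(d, length(nms)), dimnames = list(NULL, NULL, nms))
  mask <- matrix(TRUE, d[1], d[2])
  for (k in seq_along(nms)) {
    src <- if (prov[k] == "sar") sarFs else optFs
    pl <- layerData(src, nms[k])
    arr[, , k] <- pl
    mask <- mask & src@mask & is.finite(pl)
  }
  raw <- featureStack(arr, mask = mask, provenance = prov)
  minmaxNormalize(raw, robust = robust, constants = constants)
}

#' Extract all SAR-side feature layers from a covariance field
#'
#' Convenience composite running the full SAR feature chain: basis-transform
#' intensities, dB conversion, sigma PCA, RVI and the Yamaguchi powers
#' (layers sigma_pca1..k, RVI, Ps, Pd, Ph, Pv; Ph is the helix power).
#'
#' @param c3 a \code{\linkS4class{C3Field}}.
#' @param varThreshold sigma-PCA explained-variance threshold.
#' @param floorDb dB floor for zero intensities.
#' @param pcaOnDb run the PCA on dB values (default) or linear intensities.
#' @return an unnormalized \code{FeatureStack}; \code{pcaInfo} carries the
#'   sigma-PCA report.
#' @export
buildSarFeatures <- function(c3, varThreshold = 0.98, floorDb = -50,
                             pcaOnDb = TRUE) {
  p <- c3ToIntensity(c3)
  src <- if (pcaOnDb) intensityToDb(p, floorDb = floorDb) else p
  spc <- sigmaPCA(src, varThreshold = varThreshold)
  rv <- rvi(c3)
  yam <- yamaguchiDecompose(c3)
  d <- dim(c3@data)[1:2]
  layers <- list()
  for (nm in layerNames(spc)) layers[[nm]] <- layerData(spc, nm)
  layers$RVI <- rv$values
  layers$Ps <- yam@Ps; layers$Pd <- yam@Pd; layers$Ph <- yam@Pc
  layers$Pv <- yam@Pv
  mask <- c3@mask & spc@mask & rv$mask & yam@mask
  fs <- featureStack(layers, mask = mask, provenance = "sar")
  attr(fs, "pca") <- pcaInfo(spc)
  fs
}

#' Extract all optical-side feature layers
#'
#' Runs band PCA, NDVI and window entropy (layers Opband_pca1..k, NDVI, H).
#'
#' @param bands an \code{\linkS4class{OpticalBands}} with R, G, B, NIR.
#' @param varThreshold band-PCA explained-variance threshold.
#' @param textureBand band used for the entropy texture (default "R").
#' @param window,bins entropy window side length and gray-level count.
#' @return an unnormalized \code{FeatureStack} with \code{pcaInfo}.
#' @export
buildOpticalFeatures <- function(bands, varThreshold = 0.99,
                                 textureBand = "R", window = 7, bins = 32) {
  pcs <- bandPCA(bands, varThreshold = varThreshold)
  nd <- ndvi(bands)
  H <- entropyTexture(layerData(bands, textureBand), window = window,
                      bins = bins, mask = bands@mask)
  layers <- list()
  for (nm in layerNames(pcs)) layers[[nm]] <- layerData(pcs, nm)
  layers$NDVI <- nd$values
  layers$H <- H$values
  mask <- bands@mask & pcs@mask & nd$mask & H$mask
  fs <- featureStack(layers, mask = mask, provenance = "optical")
  attr(fs, "pca") <- pcaInfo(pcs)
  fs
}
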