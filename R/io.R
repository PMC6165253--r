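## Raster container: band-sequential flat binary (little-endian float64 or
## int32) with a JSON header sidecar at <path>.hdr.json recording grid shape,
## band names, dtype and nodata. Bit-exact round trips for both integer and
## floating rasters; the same container PolSARpro-style per-element readers
## expect, with an explicit header.

.hdrPath <- function(path) paste0(path, ".hdr.json")

#' Write a raster to the flat-binary container
#'
#' @param x numeric matrix, rows x cols x bands array, or integer matrix.
#' @param path output data-file path; a JSON header is written alongside at
#'   \code{<path>.hdr.json}.
#' @param bandNames optional band names (default from dimnames).
#' @param dtype "float64" or "int32" (default chosen from storage mode).
#' @param nodata nodata value recorded for integer rasters (default 0).
#' @param extra named list merged into the header (e.g. band legend,
#'   geometry tag).
#' @return \code{path}, invisibly.
#' @export
writeRaster <- function(x, path, bandNames = NULL, dtype = NULL, nodata = 0,
                        extra = list()) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  d <- dim(x)
  stopifnot(length(d) == 3L)
  if (is.null(bandNames)) bandNames <- dimnames(x)[[3]]
  if (is.null(bandNames)) bandNames <- paste0("band", seq_len(d[3]))
  if (is.null(dtype)) dtype <- if (is.integer(x)) "int32" else "float64"
  hdr <- c(list(rows = d[1], cols = d[2], bands = d[3],
                band_names = as.list(bandNames), dtype = dtype,
                byte_order = "little", interleave = "bsq", nodata = nodata),
           extra)
  jsonlite::write_json(hdr, .hdrPath(path), auto_unbox = TRUE, digits = NA)
  con <- file(path, "wb")
  on.exit(close(con))
  v <- as.vector(x)        # column-major within band, bands sequential
  if (dtype == "int32") {
    v <- as.integer(v)
    v[is.na(v)] <- as.integer(nodata)
    writeBin(v, con, size = 4L, endian = "little")
  } else {
    writeBin(as.double(v), con, size = 8L, endian = "little")
  }
  invisible(path)
}

#' Read a raster from the flat-binary container
#'
#' @param path data-file path written by \code{\link{writeRaster}}.
#' @return rows x cols x bands array with named bands; the parsed header is
#'   attached as attribute \code{"header"}.
#' @export
readRaster <- function(path) {
  hp <- .hdrPath(path)
  if (!file.exists(path)) stop("raster data file not found: ", path)
  if (!file.exists(hp)) stop("raster header not found: ", hp)
  hdr <- jsonlite::read_json(hp, simplifyVector = TRUE)
  n <- hdr$rows * hdr$cols * hdr$bands
  con <- file(path, "rb")
  on.exit(close(con))
  v <- if (hdr$dtype == "int32")
    readBin(con, integer(), n = n, size = 4L, endian = "little")
  else
    readBin(con, double(), n = n, size = 8L, endian = "little")
  if (length(v) != n)
    stop("raster ", path, " is truncated: expected ", n, " values, got ",
         length(v))
  arr <- array(v, c(hdr$rows, hdr$cols, hdr$bands),
               dimnames = list(NULL, NULL, hdr$band_names))
  attr(arr, "header") <- hdr
  arr
}

#' Write / read a covariance field in the 9-band container
#'
#' Band order is the canonical parameter order \code{c3Parameters()}.
#'
#' @param c3 a \code{\linkS4class{C3Field}}.
#' @param path data-file path.
#' @return \code{path} (write) or a \code{C3Field} (read).
#' @export
writeC3 <- function(c3, path) {
  stopifnot(is(c3, "C3Field"))
  writeRaster(c3@data, path, extra = list(looks = c3@looks,
                                          content = "C3_lexicographic"))
}

#' @rdname writeC3
#' @export
readC3 <- function(path) {
  arr <- readRaster(path)
  hdr <- attr(arr, "header")
  if (dim(arr)[3] != 9L || !identical(hdr$band_names, C3_PARAMS))
    stop("expected a 9-band covariance raster in band order ",
         paste(C3_PARAMS, collapse = ", "))
  looks <- if (!is.null(hdr$looks)) hdr$looks else 1
  c3Field(array(as.vector(arr), dim(arr), list(NULL, NULL, C3_PARAMS)),
          looks = looks)
}

## ---- configuration ----

.configSchema <- function() {
  list(seed = NULL, mode = NULL, classifier = NULL, output_dir = NULL,
       simulate = list(looks = NULL, size = NULL, field_grid = NULL,
                       train_field_fraction = NULL,
                       max_train_pixels_per_class = NULL),
       inputs = list(c3 = NULL, optical = NULL, train_csv = NULL,
                     test_csv = NULL, legend_json = NULL),
       texture = list(window = NULL, bins = NULL, band = NULL),
       pca = list(sar_threshold = NULL, optical_threshold = NULL,
                  on_db = NULL),
       normalization = list(robust = NULL),
       svm = list(cost = NULL, gamma = NULL, folds = NULL))
}

.checkKeys <- function(cfg, schema, prefix = "") {
  unknown <- setdiff(names(cfg), names(schema))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(prefix, unknown, collapse = ", "))
  for (k in names(cfg)) {
    if (is.list(schema[[k]]) && length(schema[[k]]) && is.list(cfg[[k]]))
      .checkKeys(cfg[[k]], schema[[k]], paste0(prefix, k, "."))
  }
  invisible(TRUE)
}

#' Validate a pipeline configuration
#'
#' Checks the nested key structure against the published schema (unknown
#' keys are rejected by name) and fills defaults.
#'
#' @param cfg named list as read from YAML.
#' @return validated config with defaults filled in.
#' @export
validateConfig <- function(cfg) {
  .checkKeys(cfg, .configSchema())
  defaults <- list(seed = 42L, mode = "full", classifier = "svm",
                   output_dir = "polcropsar_out")
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  if (!cfg$mode %in% names(integrationModes()))
    stop("mode must be one of: ",
         paste(names(integrationModes()), collapse = ", "))
  if (!cfg$classifier %in% c("svm", "wishart"))
    stop("classifier must be 'svm' or 'wishart'")
  if (is.null(cfg$simulate) && is.null(cfg$inputs))
    stop("config needs either a 'simulate' or an 'inputs' section")
  cfg
}

#' Read and validate a YAML pipeline configuration
#' @param path YAML file path.
#' @return validated config list.
#' @export
readConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  validateConfig(yaml::read_yaml(path))
}

#' Stable fingerprint of a configuration
#' @param cfg config list.
#' @return md5 hex string of the canonically serialized config.
#' @export
configHash <- function(cfg) {
  cfg$output_dir <- NULL      # output location does not affect the results
  tf <- tempfile()
  on.exit(unlink(tf))
  ## canonical text form: sorted, flattened key=value lines
  flat <- function(x, prefix = "") {
    if (is.list(x))
      unlist(lapply(sort(names(x)), function(k)
        flat(x[[k]], paste0(prefix, k, "."))))
    else paste0(prefix, "=", paste(format(x, digits = 17), collapse = ","))
  }
  writeLines(flat(cfg), tf)
  unname(tools::md5sum(tf))
}
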