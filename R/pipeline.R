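## End-to-end pipeline: features -> integrate -> train -> classify -> assess,
## with on-disk artifacts and a structured run log.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

.readTrainCsv <- function(path, legend) {
  df <- utils::read.csv(path)
  trainingSet(df, legend)
}

#' Run the full classification pipeline
#'
#' Executes feature extraction (SAR and optical), feature integration in the
#' configured mode, classifier training, scene classification and accuracy
#' assessment, and writes five artifacts into \code{output_dir}: the
#' normalized feature stack, the class map, the confusion-matrix CSV, the
#' accuracy-report JSON and a run log (config hash, seed, PCA explained
#' variance, chosen SVM hyperparameters). The run is a pure function of
#' (inputs, config, seed): a rerun with the same config produces an
#' identical report.
#'
#' @param cfg validated config list (see \code{\link{readConfig}}); a path
#'   to a YAML file is also accepted.
#' @return invisibly, a list with the in-memory results (stack, classMap,
#'   confusion, report, log).
#' @export
runPipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- readConfig(cfg)
  cfg <- validateConfig(cfg)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- configHash(cfg)

  dat <- .stage("load", {
    if (!is.null(cfg$simulate)) {
      sc <- cfg$simulate
      scfg <- simConfig(
        looks = if (!is.null(sc$looks)) sc$looks else 4,
        size = if (!is.null(sc$size)) unlist(sc$size) else c(128, 128),
        fieldGrid = if (!is.null(sc$field_grid)) unlist(sc$field_grid)
                    else c(8, 8),
        trainFieldFraction = if (!is.null(sc$train_field_fraction))
          sc$train_field_fraction else 0.25,
        maxTrainPixelsPerClass = if (!is.null(sc$max_train_pixels_per_class))
          sc$max_train_pixels_per_class else 400,
        seed = cfg$seed)
      generateScene(scfg)
    } else {
      inp <- cfg$inputs
      legend <- unlist(jsonlite::read_json(inp$legend_json,
                                           simplifyVector = TRUE))
      legend <- stats::setNames(as.character(legend), names(legend))
      arr <- readRaster(inp$optical)
      if (!identical(dim(arr)[1:2], dim(readRaster(inp$c3))[1:2]))
        stop("c3 and optical grids differ")
      list(c3 = readC3(inp$c3), optical = opticalBands(arr),
           train = .readTrainCsv(inp$train_csv, legend),
           test = .readTrainCsv(inp$test_csv, legend))
    }
  })

  sarTh <- if (!is.null(cfg$pca$sar_threshold)) cfg$pca$sar_threshold else 0.98
  optTh <- if (!is.null(cfg$pca$optical_threshold)) cfg$pca$optical_threshold
           else 0.99
  onDb <- if (!is.null(cfg$pca$on_db)) cfg$pca$on_db else TRUE
  win <- if (!is.null(cfg$texture$window)) cfg$texture$window else 7
  bins <- if (!is.null(cfg$texture$bins)) cfg$texture$bins else 32
  tband <- if (!is.null(cfg$texture$band)) cfg$texture$band else "R"
  robust <- isTRUE(cfg$normalization$robust)

  modeLayers <- integrationModes()[[cfg$mode]]
  sarFs <- NULL; optFs <- NULL
  if (length(modeLayers$sar))
    sarFs <- .stage("features-sar",
                    buildSarFeatures(dat$c3, varThreshold = sarTh,
                                     pcaOnDb = onDb))
  if (length(modeLayers$optical))
    optFs <- .stage("features-optical",
                    buildOpticalFeatures(dat$optical, varThreshold = optTh,
                                         textureBand = tband, window = win,
                                         bins = bins))
  stack <- .stage("integrate",
                  assembleFeatures(cfg$mode, sarFs, optFs, robust = robust))

  if (cfg$classifier == "svm") {
    svmCost <- if (!is.null(cfg$svm$cost)) unlist(cfg$svm$cost)
               else c(0.1, 1, 10, 100)
    svmGamma <- if (!is.null(cfg$svm$gamma)) unlist(cfg$svm$gamma)
                else c(0.01, 0.1, 1, 10)
    svmFolds <- if (!is.null(cfg$svm$folds)) cfg$svm$folds else 5
    handle <- .stage("train",
                     svmTrain(stack, dat$train, cost = svmCost,
                              gamma = svmGamma, folds = svmFolds,
                              seed = cfg$seed))
    map <- .stage("classify", svmPredict(stack, handle))
    chosen <- list(cost = handle$cost, gamma = handle$gamma,
                   cvAccuracy = handle$cvAccuracy)
  } else {
    model <- .stage("train", wishartTrain(dat$c3, dat$train))
    map <- .stage("classify", wishartClassify(dat$c3, model))
    chosen <- list(epsilon = model@epsilon)
  }

  cm <- .stage("assess", confusionCounts(map, dat$test))
  report <- accuracyMetrics(cm)

  od <- cfg$output_dir
  .stage("write", {
    writeRaster(stack@data, file.path(od, "feature_stack.dat"),
                extra = list(config_hash = hash, mode = cfg$mode))
    writeRaster(classLabels(map), file.path(od, "class_map.dat"),
                dtype = "int32",
                extra = list(config_hash = hash,
                             legend = as.list(classLegend(map))))
    writeConfusionCsv(cm, file.path(od, "confusion.csv"))
    jsonlite::write_json(
      list(config_hash = hash, overall_accuracy = report$overallAccuracy,
           kappa = report$kappa, ua = as.list(report$ua),
           pa = as.list(report$pa), tp_rate = as.list(report$tpRate),
           fn_rate = as.list(report$fnRate), fp_rate = as.list(report$fpRate),
           tn_rate = as.list(report$tnRate)),
      file.path(od, "report.json"), auto_unbox = TRUE, digits = NA)
  })

  log <- list(
    config_hash = hash, seed = cfg$seed, mode = cfg$mode,
    classifier = cfg$classifier, n_layers = dim(stack@data)[3],
    layers = layerNames(stack),
    sar_pca_explained = if (!is.null(sarFs)) pcaInfo(sarFs)$explained,
    optical_pca_explained = if (!is.null(optFs)) pcaInfo(optFs)$explained,
    classifier_params = chosen)
  jsonlite::write_json(log, file.path(od, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(stack = stack, classMap = map, confusion = cm,
                 report = report, log = log))
}
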