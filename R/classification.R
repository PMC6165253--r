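#' Labeled training/testing pixel set
#'
#' @slot pixels data.frame with integer columns \code{row}, \code{col},
#'   \code{classId} and optional \code{plotId}.
#' @slot legend named character vector mapping class id to name.
#' @exportClass TrainingSet
setClass("TrainingSet",
         representation(pixels = "data.frame", legend = "character"))

setValidity("TrainingSet", function(object) {
  px <- object@pixels
  need <- c("row", "col", "classId")
  if (!all(need %in% names(px))) return("pixels needs row, col, classId")
  if (!all(as.character(unique(px$classId)) %in% names(object@legend)))
    return("classId values must appear in the legend")
  if (length(unique(px$classId)) < 2) return("at least 2 classes required")
  TRUE
})

#' Construct a TrainingSet
#' @param pixels data.frame with columns row, col, classId (and optionally
#'   plotId).
#' @param legend named character vector (names = class ids as strings).
#' @return a \code{TrainingSet}.
#' @export
trainingSet <- function(pixels, legend) {
  if (is.null(pixels$plotId)) pixels$plotId <- 1L
  new("TrainingSet", pixels = pixels, legend = legend)
}

setMethod("show", "TrainingSet", function(object) {
  tb <- table(factor(object@pixels$classId, levels = names(object@legend)))
  cat(sprintf("TrainingSet: %d pixels, %d classes\n",
              nrow(object@pixels), length(object@legend)))
  print(stats::setNames(as.integer(tb), object@legend))
})

.pixelIndex <- function(train, nrows) {
  (train@pixels$col - 1L) * nrows + train@pixels$row
}

## ---- complex Wishart maximum-likelihood classifier ----

#' Train a complex-Wishart class model
#'
#' The class model is the arithmetic mean covariance matrix of the training
#' pixels of each class. If any class mean is singular, a small diagonal
#' loading epsilon = 1e-9 * mean(span) is added to every class.
#'
#' @param c3 a \code{\linkS4class{C3Field}}.
#' @param train a \code{\linkS4class{TrainingSet}}; every class needs at
#'   least 9 training pixels.
#' @return a \code{\linkS4class{WishartModel}}.
#' @export
wishartTrain <- function(c3, train) {
  stopifnot(is(c3, "C3Field"), is(train, "TrainingSet"))
  d <- dim(c3@data)
  X <- matrix(c3@data, d[1] * d[2], 9)
  idx <- .pixelIndex(train, d[1])
  if (any(!c3@mask[cbind(train@pixels$row, train@pixels$col)]))
    stop("training set references invalid (masked) pixels")
  ids <- names(train@legend)
  sig <- vector("list", length(ids))
  counts <- integer(length(ids))
  for (k in seq_along(ids)) {
    sel <- idx[train@pixels$classId == as.integer(ids[k])]
    if (length(sel) == 0)
      stop("class '", train@legend[k], "' has no training pixels")
    if (length(sel) < 9)
      stop("class '", train@legend[k], "' has fewer than 9 training pixels")
    sig[[k]] <- .paramsToMatrix(colMeans(X[sel, , drop = FALSE]))
    counts[k] <- length(sel)
  }
  meanSpan <- mean(vapply(sig, function(S) Re(sum(diag(S))), numeric(1)))
  eps <- 0
  singular <- any(vapply(sig, function(S)
    Mod(.cdet3(S)) < 1e-12 * max(Mod(S))^3, logical(1)))
  if (singular) {
    eps <- 1e-9 * meanSpan
    sig <- lapply(sig, function(S) S + eps * diag(3))
  }
  new("WishartModel", sigma = sig, counts = counts, epsilon = eps,
      legend = train@legend)
}

#' Classify a covariance field with the Wishart maximum-likelihood rule
#'
#' Assigns each valid pixel to the class m minimizing the Wishart distance
#' d_m(C) = ln det(Sigma_m) + tr(Sigma_m^-1 C). Ties go to the lowest class
#' id; pixels with a non-finite distance become nodata and are counted in the
#' provenance.
#'
#' @param c3 a \code{\linkS4class{C3Field}}.
#' @param model a \code{\linkS4class{WishartModel}}.
#' @return a \code{\linkS4class{ClassMap}}.
#' @export
wishartClassify <- function(c3, model) {
  stopifnot(is(c3, "C3Field"), is(model, "WishartModel"))
  d <- dim(c3@data)
  X <- matrix(c3@data, d[1] * d[2], 9)
  ids <- as.integer(names(model@legend))
  ## tr(Sigma^-1 C) is a real linear form in the 9 parameter planes because
  ## both matrices are Hermitian: weights (A11, A22, A33, 2ReA12, 2ImA12, ...)
  ## with A = Sigma^-1
  D <- matrix(Inf, nrow(X), length(ids))
  for (k in seq_along(ids)) {
    S <- model@sigma[[k]]
    A <- solve(S)
    w <- c(Re(A[1, 1]), Re(A[2, 2]), Re(A[3, 3]),
           2 * Re(A[1, 2]), 2 * Im(A[1, 2]),
           2 * Re(A[1, 3]), 2 * Im(A[1, 3]),
           2 * Re(A[2, 3]), 2 * Im(A[2, 3]))
    ldet <- log(Mod(.cdet3(S)))
    D[, k] <- ldet + X %*% w
  }
  finite <- rowSums(is.finite(D)) == length(ids)
  best <- max.col(-D, ties.method = "first")   # lowest class id wins ties
  lab <- ids[best]
  lab[!finite | !as.vector(c3@mask)] <- 0L
  nNonFinite <- sum(!finite & as.vector(c3@mask))
  classMap(matrix(lab, d[1], d[2]), model@legend,
           provenance = list(model = "wishart", nNonFinite = nNonFinite))
}

## ---- SVM (RBF) on feature stacks ----

.stackTrainingMatrix <- function(stack, train) {
  d <- dim(stack@data)
  X <- matrix(stack@data, d[1] * d[2], d[3])
  colnames(X) <- layerNames(stack)
  idx <- .pixelIndex(train, d[1])
  ok <- stack@mask[cbind(train@pixels$row, train@pixels$col)]
  if (!all(ok)) {
    warning(sum(!ok), " training pixel(s) fall outside the valid mask; dropped")
    idx <- idx[ok]
  }
  list(X = X[idx, , drop = FALSE],
       y = train@pixels$classId[ok])
}

#' Train an RBF-kernel SVM on a feature stack
#'
#' Fits a support vector machine with the radial basis function kernel on
#' the training pixels of a normalized feature stack. Cost and kernel width
#' gamma are chosen by k-fold cross-validated accuracy over a log grid; the
#' chosen values, the grid and the CV accuracy are kept on the returned
#' handle. Deterministic for a fixed seed.
#'
#' @param stack normalized \code{\linkS4class{FeatureStack}}.
#' @param train \code{\linkS4class{TrainingSet}} with >= 2 classes.
#' @param cost,gamma hyperparameter grids (defaults 0.1/1/10/100 and
#'   0.01/0.1/1/10).
#' @param folds number of CV folds (default 5).
#' @param seed RNG seed for the fold assignment.
#' @return an object of class \code{svmHandle}: list with the fitted e1071
#'   model, layer names, chosen hyperparameters, CV table and seed.
#' @export
svmTrain <- function(stack, train, cost = c(0.1, 1, 10, 100),
                     gamma = c(0.01, 0.1, 1, 10), folds = 5, seed = 1) {
  stopifnot(is(stack, "FeatureStack"), is(train, "TrainingSet"))
  if (!length(stack@normalization))
    warning("training on an unnormalized stack")
  tm <- .stackTrainingMatrix(stack, train)
  y <- factor(tm$y, levels = names(train@legend))
  if (nlevels(droplevels(y)) < 2) stop("SVM training needs >= 2 classes")
  n <- length(y)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(folds), n))
  grid <- expand.grid(cost = cost, gamma = gamma)
  grid$cvAccuracy <- NA_real_
  for (g in seq_len(nrow(grid))) {
    acc <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- fold != f
      fit <- e1071::svm(tm$X[tr, , drop = FALSE], droplevels(y[tr]),
                        kernel = "radial", cost = grid$cost[g],
                        gamma = grid$gamma[g], scale = FALSE)
      pr <- stats::predict(fit, tm$X[!tr, , drop = FALSE])
      acc[f] <- mean(as.character(pr) == as.character(y[!tr]))
    }
    grid$cvAccuracy[g] <- mean(acc)
  }
  best <- which.max(grid$cvAccuracy)
  model <- e1071::svm(tm$X, droplevels(y), kernel = "radial",
                      cost = grid$cost[best], gamma = grid$gamma[best],
                      scale = FALSE)
  structure(list(model = model, layers = layerNames(stack),
                 legend = train@legend,
                 cost = grid$cost[best], gamma = grid$gamma[best],
                 cvAccuracy = grid$cvAccuracy[best], cvGrid = grid,
                 folds = folds, seed = seed),
            class = "svmHandle")
}

#' @export
print.svmHandle <- function(x, ...) {
  cat(sprintf("RBF-SVM handle: %d layers, cost = %g, gamma = %g, CV accuracy = %.3f\n",
              length(x$layers), x$cost, x$gamma, x$cvAccuracy))
  invisible(x)
}

#' Predict a class map from a feature stack with a trained SVM
#'
#' Layers are aligned to the training layers by name (order-independent);
#' a missing or extra layer is an error listing the difference. Invalid
#' pixels become nodata.
#'
#' @param stack normalized \code{\linkS4class{FeatureStack}}.
#' @param handle an \code{svmHandle} from \code{\link{svmTrain}}.
#' @return a \code{\linkS4class{ClassMap}}.
#' @export
svmPredict <- function(stack, handle) {
  stopifnot(is(stack, "FeatureStack"), inherits(handle, "svmHandle"))
  have <- layerNames(stack)
  if (!setequal(have, handle$layers)) {
    stop("layer mismatch; missing: ",
         paste(setdiff(handle$layers, have), collapse = ", "),
         "; unexpected: ", paste(setdiff(have, handle$layers), collapse = ", "))
  }
  d <- dim(stack@data)
  X <- matrix(stack@data, d[1] * d[2], d[3])
  colnames(X) <- have
  X <- X[, handle$layers, drop = FALSE]
  lab <- rep(0L, nrow(X))
  ok <- as.vector(stack@mask) & rowSums(!is.finite(X)) == 0
  if (any(ok)) {
    pr <- stats::predict(handle$model, X[ok, , drop = FALSE])
    lab[ok] <- as.integer(as.character(pr))
  }
  classMap(matrix(lab, d[1], d[2]), handle$legend,
           provenance = list(model = "svm", cost = handle$cost,
                             gamma = handle$gamma))
}
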