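#' Build a confusion matrix from a classification and a reference
#'
#' Counts[i, j] is the number of pixels classified as class i whose reference
#' class is j (rows = classified, columns = reference; user's accuracy is a
#' row statistic, producer's accuracy a column statistic). Nodata pixels on
#' either side are excluded; an empty overlap or a legend mismatch is an
#' error.
#'
#' @param pred a \code{\linkS4class{ClassMap}}.
#' @param ref a \code{ClassMap} on the same grid, or a
#'   \code{\linkS4class{TrainingSet}} of reference pixels.
#' @return a \code{\linkS4class{ConfusionMatrix}}.
#' @export
confusionCounts <- function(pred, ref) {
  stopifnot(is(pred, "ClassMap"))
  if (is(ref, "TrainingSet")) {
    if (!identical(unname(ref@legend[names(pred@legend)]),
                   unname(pred@legend)))
      stop("legend mismatch between prediction and reference")
    p <- pred@labels[cbind(ref@pixels$row, ref@pixels$col)]
    r <- ref@pixels$classId
  } else if (is(ref, "ClassMap")) {
    if (!identical(dim(pred@labels), dim(ref@labels)))
      stop("prediction and reference grids differ")
    if (!identical(pred@legend, ref@legend))
      stop("legend mismatch between prediction and reference")
    p <- as.vector(pred@labels)
    r <- as.vector(ref@labels)
  } else stop("ref must be a ClassMap or a TrainingSet")
  keep <- p != 0L & r != 0L
  if (!any(keep)) stop("empty overlap between prediction and reference")
  lev <- names(pred@legend)
  tab <- table(classified = factor(p[keep], levels = lev),
               reference = factor(r[keep], levels = lev))
  confusionMatrix(unclass(as.matrix(tab)), legend = pred@legend)
}

#' Accuracy statistics of a confusion matrix
#'
#' Computes overall accuracy OA = trace/total, the kappa coefficient
#' kappa = (Po - Pe)/(1 - Pe) with Pe the chance agreement from the
#' marginals, per-class user's accuracy UA_i = counts[i,i]/rowsum_i and
#' producer's accuracy PA_i = counts[i,i]/colsum_i, and one-vs-rest rates:
#' TP rate = PA_i, FN rate = 1 - PA_i,
#' FP rate = (rowsum_i - counts[i,i])/(total - colsum_i), TN rate = 1 - FP
#' rate. A class with an empty row (column) has undefined UA (PA); it is
#' reported as NA and flagged rather than propagated as NaN.
#'
#' @param cm a \code{\linkS4class{ConfusionMatrix}}.
#' @return list with elements \code{overallAccuracy}, \code{kappa},
#'   \code{ua}, \code{pa}, \code{tpRate}, \code{fnRate}, \code{fpRate},
#'   \code{tnRate} (named per class, fractions in [0,1]) and
#'   \code{undefined} (character vector of flagged classes).
#' @export
accuracyMetrics <- function(cm) {
  stopifnot(is(cm, "ConfusionMatrix"))
  m <- cm@counts
  total <- sum(m)
  dg <- diag(m)
  rs <- rowSums(m)
  cs <- colSums(m)
  oa <- sum(dg) / total
  pe <- sum(rs * cs) / total^2
  kappa <- (oa - pe) / (1 - pe)
  ua <- ifelse(rs > 0, dg / rs, NA_real_)
  pa <- ifelse(cs > 0, dg / cs, NA_real_)
  fp <- ifelse(total - cs > 0, (rs - dg) / (total - cs), NA_real_)
  undef <- cm@legend[rs == 0 | cs == 0]
  nm <- unname(cm@legend)
  out <- list(overallAccuracy = oa, kappa = kappa,
              ua = stats::setNames(ua, nm), pa = stats::setNames(pa, nm),
              tpRate = stats::setNames(pa, nm),
              fnRate = stats::setNames(1 - pa, nm),
              fpRate = stats::setNames(fp, nm),
              tnRate = stats::setNames(1 - fp, nm),
              undefined = unname(undef))
  class(out) <- "accuracyReport"
  out
}

#' @export
print.accuracyReport <- function(x, digits = 2, ...) {
  cat(sprintf("Overall accuracy: %.4f%%   kappa: %.4f\n",
              100 * x$overallAccuracy, x$kappa))
  tab <- round(100 * cbind(`UA (%)` = x$ua, `PA (%)` = x$pa), digits)
  print(tab)
  if (length(x$undefined))
    cat("undefined UA/PA for:", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' Read a legend-labeled confusion-matrix CSV
#'
#' The expected layout is a square count table whose first column holds the
#' classified-class names and whose header holds the reference-class names,
#' as written by \code{\link{writeConfusionCsv}}.
#'
#' @param path CSV file path.
#' @return a \code{\linkS4class{ConfusionMatrix}}.
#' @export
readConfusionCsv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  legend <- rownames(m)
  names(legend) <- seq_along(legend)
  confusionMatrix(m, legend = legend)
}

#' Write a confusion matrix as a legend-labeled CSV
#' @param cm a \code{\linkS4class{ConfusionMatrix}}.
#' @param path output CSV path.
#' @export
writeConfusionCsv <- function(cm, path) {
  m <- cm@counts
  df <- data.frame(class = unname(cm@legend), m, check.names = FALSE)
  colnames(df) <- c("class", unname(cm@legend))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
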