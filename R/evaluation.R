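#' Score a segmentation against ground truth inside the FOV
#'
#' Confusion counts are restricted to FOV pixels; vessel is the positive
#' class. Accuracy is the fraction of correctly classified FOV pixels,
#' sensitivity the vessel true-positive rate tp/(tp + fn), specificity the
#' background true-negative rate tn/(tn + fp). When the truth contains no
#' vessel pixel inside the FOV, sensitivity is undefined and reported as NA.
#'
#' @param pred logical predicted vessel map, or a [SegmentationResult-class].
#' @param truth logical ground-truth vessel map.
#' @param fov logical FOV mask; defaults to the full frame.
#' @return A [MetricsReport-class].
#' @examples
#' truth <- matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2)
#' scoreSegmentation(truth, truth)   # perfect: all rates 1
#' @export
scoreSegmentation <- function(pred, truth, fov = NULL) {
  if (is(pred, "SegmentationResult")) pred <- vesselMap(pred)
  if (is.null(fov)) fov <- matrix(TRUE, nrow(truth), ncol(truth))
  if (!identical(dim(pred), dim(truth)) || !identical(dim(pred), dim(fov)))
    stop("pred, truth and fov must share one shape")
  if (!any(fov)) stop("fov mask is empty")
  p <- pred[fov]; t <- truth[fov]
  tp <- sum(p & t); fp <- sum(p & !t)
  fn <- sum(!p & t); tn <- sum(!p & !t)
  nFov <- length(p)
  new("MetricsReport",
      accuracy = (tp + tn) / nFov,
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
      tp = as.integer(tp), fp = as.integer(fp), tn = as.integer(tn),
      fn = as.integer(fn), nFov = as.integer(nFov))
}

#' Tabulate per-sample metrics with an average row
#'
#' @param reports named list of [MetricsReport-class] objects.
#' @return data.frame with columns sample, accuracy, sensitivity,
#'   specificity and a final "mean" row averaging samples equally (NA
#'   sensitivities are dropped from the average).
#' @export
metricsTable <- function(reports) {
  if (length(reports) == 0L) stop("no metrics to tabulate")
  ids <- names(reports)
  if (is.null(ids)) ids <- as.character(seq_along(reports))
  df <- data.frame(
    sample = ids,
    accuracy = vapply(reports, function(r) r@accuracy, 0),
    sensitivity = vapply(reports, function(r) r@sensitivity, 0),
    specificity = vapply(reports, function(r) r@specificity, 0),
    row.names = NULL, stringsAsFactors = FALSE)
  rbind(df, data.frame(sample = "mean",
                       accuracy = mean(df$accuracy),
                       sensitivity = mean(df$sensitivity, na.rm = TRUE),
                       specificity = mean(df$specificity, na.rm = TRUE)))
}

#' Write a metrics table as CSV and aligned text
#'
#' The text layout mirrors the usual benchmark tables: method rows with
#' average accuracy, sensitivity and specificity columns.
#'
#' @param table data.frame from [metricsTable()].
#' @param csvPath,txtPath output paths; either may be NULL to skip.
#' @return `table`, invisibly.
#' @export
writeMetricsReport <- function(table, csvPath = NULL, txtPath = NULL) {
  if (!is.null(csvPath))
    utils::write.csv(table, csvPath, row.names = FALSE)
  if (!is.null(txtPath)) {
    fmt <- function(x) ifelse(is.na(x), "  --  ", sprintf("%.4f", x))
    lines <- c(
      sprintf("%-12s %-16s %-12s %-12s", "Sample", "Average accuracy",
              "Sensitivity", "Specificity"),
      sprintf("%-12s %-16s %-12s %-12s", table$sample, fmt(table$accuracy),
              fmt(table$sensitivity), fmt(table$specificity)))
    writeLines(lines, txtPath)
  }
  invisible(table)
}
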