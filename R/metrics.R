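#' Confusion counts with RHD as the positive class
#'
#' @param y_true,y_pred Equal-length label vectors (`"RHD"`/`"HC"`).
#' @return List of class `confusion_counts`: `Tp`, `Fp`, `Fn`, `Tn`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("confusion: length mismatch", call. = FALSE)
  }
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  structure(
    list(
      Tp = sum(y_true == "RHD" & y_pred == "RHD"),
      Fp = sum(y_true == "HC" & y_pred == "RHD"),
      Fn = sum(y_true == "RHD" & y_pred == "HC"),
      Tn = sum(y_true == "HC" & y_pred == "HC")
    ),
    class = "confusion_counts"
  )
}

#' Screening metrics from confusion counts
#'
#' precision = Tp/(Tp+Fp), recall (sensitivity to disease) = Tp/(Tp+Fn),
#' f1 = harmonic mean of precision and recall, specificity = Tn/(Tn+Fp).
#' A zero denominator yields 0 for that metric together with an
#' `undefined` flag naming it.
#'
#' @param counts A `confusion_counts` object.
#' @param warn Emit an R warning when a metric is undefined (default TRUE;
#'   the grid-search inner loop silences it and relies on the flag).
#' @return List of class `metric_set`: `precision`, `recall`, `f1`,
#'   `specificity` in `[0, 1]`, plus `undefined` (character vector).
#' @export
compute_metrics <- function(counts, warn = TRUE) {
  stopifnot(inherits(counts, "confusion_counts"))
  undefined <- character(0)
  safe_div <- function(num, den, name) {
    if (den == 0) {
      undefined <<- c(undefined, name)
      0
    } else {
      num / den
    }
  }
  precision <- safe_div(counts$Tp, counts$Tp + counts$Fp, "precision")
  recall <- safe_div(counts$Tp, counts$Tp + counts$Fn, "recall")
  f1 <- if (precision + recall == 0) {
    undefined <- c(undefined, "f1")
    0
  } else {
    2 * precision * recall / (precision + recall)
  }
  specificity <- safe_div(counts$Tn, counts$Tn + counts$Fp, "specificity")
  if (warn && length(undefined) > 0) {
    warning("metric(s) undefined (zero denominator), reported as 0: ",
            paste(unique(undefined), collapse = ", "), call. = FALSE)
  }
  structure(
    list(precision = precision, recall = recall, f1 = f1,
         specificity = specificity, undefined = unique(undefined)),
    class = "metric_set"
  )
}
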