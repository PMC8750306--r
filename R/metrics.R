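#' One-vs-rest confusion counts
#'
#' Builds the 4-way (or k-way) count table of truth vs prediction and
#' derives per-class TP/TN/FP/FN counts (one-vs-rest).
#'
#' @param truth,pred Character/factor vectors of equal length.
#' @param classes Optional class universe (defaults to the union observed).
#' @return A `confusion_matrix` tibble: `class`, `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(truth, pred, classes = NULL) {
  truth <- as.character(truth); pred <- as.character(pred)
  if (length(truth) != length(pred)) abort("truth and pred lengths differ")
  if (is.null(classes)) classes <- sort(union(truth, pred))
  out <- map(classes, function(cl) {
    tibble(
      class = cl,
      tp = sum(truth == cl & pred == cl),
      tn = sum(truth != cl & pred != cl),
      fp = sum(truth != cl & pred == cl),
      fn = sum(truth == cl & pred != cl)
    )
  }) %>% list_rbind()
  class(out) <- c("confusion_matrix", class(out))
  out
}

#' Classification performance metrics
#'
#' Per class (one-vs-rest): sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, accuracy `(TP+TN)/(TP+TN+FP+FN)` and error rate
#' `1 - accuracy`. Degenerate denominators yield `NA` with a warning.
#'
#' @param cm A `confusion_matrix` from [confusion_counts()].
#' @return Tibble with the four metrics added per class.
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  safe_div <- function(num, den, what) {
    bad <- den == 0
    if (any(bad)) {
      warn(sprintf("%s undefined for class(es): %s",
                   what, paste(cm$class[bad], collapse = ", ")))
    }
    ifelse(bad, NA_real_, num / den)
  }
  cm %>%
    mutate(
      sensitivity = safe_div(.data$tp, .data$tp + .data$fn, "sensitivity"),
      specificity = safe_div(.data$tn, .data$tn + .data$fp, "specificity"),
      accuracy = (.data$tp + .data$tn) / (.data$tp + .data$tn + .data$fp + .data$fn),
      error = 1 - .data$accuracy
    )
}
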