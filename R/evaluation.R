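# Half-up decimal rounding (base round() is banker's): 86.65 -> 86.7.
round_half_up <- function(x, digits = 1L) {
  f <- 10^digits
  floor(x * f + 0.5) / f
}

#' Three-class confusion matrix (predicted x true)
#'
#' Rows are predicted labels, columns true labels, both over `{MI, MO, TO}`;
#' near-total regression (NT) in the truth is counted in the MO column.
#' Samples are aligned by ID.
#'
#' @param pred character vector of predicted labels in `{MI, MO, TO}`, named
#'   by sample ID.
#' @param truth named Dworak grade factor ([dworak_labels()]), same sample
#'   set as `pred`.
#' @return 3x3 integer matrix of class `crt_confusion`.
#' @export
confusion_matrix3 <- function(pred, truth) {
  if (is.null(names(pred)) || is.null(names(truth)))
    abort_alignment("pred and truth must be named by sample ID")
  if (!setequal(names(pred), names(truth)) ||
      anyDuplicated(names(pred)) || anyDuplicated(names(truth)))
    abort_alignment("pred and truth sample sets differ")
  pred <- pred[names(truth)]
  if (!all(pred %in% MULTICLASS_LABELS))
    abort_eval("predicted labels must be in {MI, MO, TO}")
  true3 <- as.character(truth)
  true3[true3 == "NT"] <- "MO"
  cm <- table(factor(pred, levels = MULTICLASS_LABELS),
              factor(true3, levels = MULTICLASS_LABELS))
  m <- matrix(as.integer(cm), 3L, 3L,
              dimnames = list(predicted = MULTICLASS_LABELS,
                              true = MULTICLASS_LABELS))
  structure(m, class = c("crt_confusion", class(m)))
}

# build a crt_confusion directly from printed counts (rows predicted,
# columns true, order MI, MO, TO)
as_confusion <- function(counts) {
  m <- matrix(as.integer(counts), 3L, 3L, byrow = TRUE,
              dimnames = list(predicted = MULTICLASS_LABELS,
                              true = MULTICLASS_LABELS))
  if (any(m < 0)) abort_eval("confusion counts must be non-negative")
  structure(m, class = c("crt_confusion", class(m)))
}

#' Per-class sensitivity from a confusion matrix
#'
#' Sensitivity of a class is the correct predictions for that class divided
#' by its true member count: `100 * cm[cls, cls] / colSums(cm)[cls]`,
#' reported as a percentage rounded half-up to one decimal.
#'
#' @param cm a `crt_confusion`.
#' @param cls one of `"MI"`, `"MO"`, `"TO"`.
#' @return percentage (one decimal), or `NA` with a warning when the class
#'   has no true members.
#' @export
class_sensitivity <- function(cm, cls = MULTICLASS_LABELS) {
  cls <- match.arg(cls, MULTICLASS_LABELS)
  total <- sum(cm[, cls])
  if (total == 0L) {
    warning(sprintf("no true %s samples: sensitivity undefined", cls))
    return(NA_real_)
  }
  round_half_up(100 * cm[cls, cls] / total, 1L)
}

#' Overall accuracy from a confusion matrix
#'
#' `100 * trace / total`, rounded half-up to one decimal.
#'
#' @param cm a `crt_confusion`.
#' @return percentage (one decimal).
#' @export
overall_accuracy <- function(cm) {
  total <- sum(cm)
  if (total == 0L) abort_eval("empty confusion matrix")
  round_half_up(100 * sum(diag(cm)) / total, 1L)
}

#' Full evaluation report
#'
#' Headline metrics are the per-class sensitivities and overall accuracy;
#' per-class specificity and precision are included as an extended section.
#'
#' @param cm a `crt_confusion`.
#' @return list with `confusion`, `overall_accuracy`, `sensitivity`,
#'   `specificity`, `precision` (the last two unrounded fractions).
#' @export
evaluation_report <- function(cm) {
  sens <- vapply(MULTICLASS_LABELS, function(cl)
    suppressWarnings(class_sensitivity(cm, cl)), numeric(1L))
  spec <- vapply(MULTICLASS_LABELS, function(cl) {
    tn <- sum(cm) - sum(cm[cl, ]) - sum(cm[, cl]) + cm[cl, cl]
    neg <- sum(cm) - sum(cm[, cl])
    if (neg == 0L) NA_real_ else tn / neg
  }, numeric(1L))
  prec <- vapply(MULTICLASS_LABELS, function(cl) {
    if (sum(cm[cl, ]) == 0L) NA_real_ else cm[cl, cl] / sum(cm[cl, ])
  }, numeric(1L))
  list(confusion = cm, overall_accuracy = overall_accuracy(cm),
       sensitivity = sens, specificity = spec, precision = prec)
}

#' @export
print.crt_confusion <- function(x, ...) {
  cat("Confusion matrix (rows = predicted, cols = true; NT counted as MO)\n")
  print(unclass(x))
  invisible(x)
}
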