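# Precision/recall evaluation against reference grades.

#' Evaluation report from a confusion matrix
#'
#' Rows are the reference (expert-consensus) grade, columns the system
#' classification. Per-class precision is the diagonal count over the column
#' sum (correct over all cases classified into the class), per-class recall
#' is the diagonal count over the row sum (correct over all true cases of
#' the class), and overall precision is the trace over the total. A class
#' with a zero denominator is reported as \code{NA} (undefined).
#'
#' @param mat 4x4 non-negative count matrix, rows/cols in
#'   \code{gradeLevels()} order.
#' @return An \linkS4class{EvaluationReport}.
#' @examples
#' m <- diag(c(10, 8, 5, 2))
#' overallPrecision(evaluationFromConfusion(m))
#' @export
evaluationFromConfusion <- function(mat) {
  mat <- as.matrix(mat)
  stopifnot(identical(dim(mat), c(4L, 4L)), all(mat >= 0))
  dimnames(mat) <- list(reference = gradeLevels(), system = gradeLevels())
  colSumsV <- colSums(mat); rowSumsV <- rowSums(mat)
  prec <- ifelse(colSumsV > 0, diag(mat) / colSumsV, NA_real_)
  rec <- ifelse(rowSumsV > 0, diag(mat) / rowSumsV, NA_real_)
  total <- sum(mat)
  new("EvaluationReport", confusion = mat,
      precision = stats::setNames(prec, gradeLevels()),
      recall = stats::setNames(rec, gradeLevels()),
      overallPrecision = if (total > 0) sum(diag(mat)) / total else NA_real_,
      nCases = as.integer(total))
}

#' Evaluate predicted grades against reference grades
#'
#' Tabulates the confusion matrix (reference in rows, prediction in columns)
#' and computes per-class precision/recall and overall precision. The result
#' is invariant under any joint permutation of the (prediction, reference)
#' pairs.
#'
#' @param predicted,reference equal-length grade vectors over
#'   \code{gradeLevels()}.
#' @return An \linkS4class{EvaluationReport}.
#' @export
evaluateGrading <- function(predicted, reference) {
  predicted <- factor(as.character(predicted), levels = gradeLevels())
  reference <- factor(as.character(reference), levels = gradeLevels())
  if (length(predicted) != length(reference))
    stop("predicted and reference must have equal length")
  if (anyNA(predicted) || anyNA(reference))
    stop("grades must all be in gradeLevels()")
  evaluationFromConfusion(unclass(table(reference, predicted)))
}
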