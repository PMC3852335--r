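# Accessor and show methods.

#' @rdname accessors
#' @export
setMethod("pixels", "BiopsyImage", function(object) object@pixels)

#' @rdname accessors
#' @export
setMethod("imageGrade", "BiopsyImage", function(object) object@grade)

#' @rdname accessors
#' @export
setMethod("sourceId", "BiopsyImage", function(object) object@sourceId)

#' @rdname accessors
#' @export
setMethod("vertices", "Boundary", function(object) object@vertices)

#' @rdname accessors
#' @export
setMethod("isClosed", "Boundary", function(object) object@closed)

#' @rdname accessors
#' @export
setMethod("crypts", "ContourSet", function(object) object@crypts)

#' @rdname accessors
#' @export
setMethod("muscularis", "ContourSet", function(object) object@muscularis)

#' @rdname accessors
#' @export
setMethod("cryptBoundaries", "GroundTruth", function(object) object@boundaries)

#' @rdname accessors
#' @export
setMethod("cryptCentroids", "GroundTruth", function(object) object@centroids)

#' @rdname accessors
#' @export
setMethod("muscularis", "GroundTruth", function(object) object@muscularis)

#' @rdname accessors
#' @export
setMethod("imageGrade", "GroundTruth", function(object) object@grade)

#' @rdname accessors
#' @export
setMethod("confusion", "EvaluationReport", function(object) object@confusion)

#' @rdname accessors
#' @export
setMethod("precision", "EvaluationReport", function(object) object@precision)

#' @rdname accessors
#' @export
setMethod("recall", "EvaluationReport", function(object) object@recall)

#' @rdname accessors
#' @export
setMethod("overallPrecision", "EvaluationReport",
          function(object) object@overallPrecision)

setMethod("show", "BiopsyImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("BiopsyImage %dx%d px, grade %s, source '%s'\n",
              d[2L], d[1L], object@grade, object@sourceId))
})

setMethod("show", "Boundary", function(object) {
  cat(sprintf("%s Boundary with %d vertices\n",
              if (object@closed) "closed" else "open", nrow(object@vertices)))
})

setMethod("show", "ContourSet", function(object) {
  cat(sprintf("ContourSet: %d crypt(s), muscularis %s\n",
              length(object@crypts),
              if (is.null(object@muscularis)) "absent" else "present"))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: grade %s, %d crypt(s)\n",
              object@grade, length(object@boundaries)))
})

setMethod("show", "GradeParams", function(object) {
  cat(sprintf(
    "GradeParams %s: distortion %.2f, count %d-%d, basal gap %.0f px (±%.0f%%), spacing jitter %.0f%%\n",
    object@grade, object@boundaryDistortion, object@cryptCountRange[1L],
    object@cryptCountRange[2L], object@basalGap, 100 * object@gapJitter,
    100 * object@spacingJitter))
})

setMethod("show", "PNNModel", function(object) {
  tab <- table(droplevels(object@labels))
  cat(sprintf("PNNModel: %d stored pattern(s) [%s], sigma %.4g\n",
              nrow(object@patterns),
              paste(names(tab), tab, sep = ":", collapse = ", "),
              object@sigma))
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport on %d case(s); overall precision %.2f%%\n",
              object@nCases, 100 * object@overallPrecision))
  print(object@confusion)
  cat("precision:", paste(sprintf("%s %.2f%%", names(object@precision),
                                  100 * object@precision), collapse = ", "), "\n")
  cat("recall:   ", paste(sprintf("%s %.2f%%", names(object@recall),
                                  100 * object@recall), collapse = ", "), "\n")
})
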