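#' @title Accessor generics
#' @description Read-only accessors for the package's S4 containers.
#' @param object an S4 object from this package.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))

#' @rdname accessors
#' @export
setGeneric("imageGrade", function(object) standardGeneric("imageGrade"))

#' @rdname accessors
#' @export
setGeneric("sourceId", function(object) standardGeneric("sourceId"))

#' @rdname accessors
#' @export
setGeneric("vertices", function(object) standardGeneric("vertices"))

#' @rdname accessors
#' @export
setGeneric("isClosed", function(object) standardGeneric("isClosed"))

#' @rdname accessors
#' @export
setGeneric("crypts", function(object) standardGeneric("crypts"))

#' @rdname accessors
#' @export
setGeneric("muscularis", function(object) standardGeneric("muscularis"))

#' @rdname accessors
#' @export
setGeneric("cryptBoundaries", function(object) standardGeneric("cryptBoundaries"))

#' @rdname accessors
#' @export
setGeneric("cryptCentroids", function(object) standardGeneric("cryptCentroids"))

#' @rdname accessors
#' @export
setGeneric("confusion", function(object) standardGeneric("confusion"))

#' @rdname accessors
#' @export
setGeneric("precision", function(object) standardGeneric("precision"))

#' @rdname accessors
#' @export
setGeneric("recall", function(object) standardGeneric("recall"))

#' @rdname accessors
#' @export
setGeneric("overallPrecision", function(object) standardGeneric("overallPrecision"))
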