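#' Grade levels for crypt architectural distortion
#'
#' The four-level grading scheme used throughout the package: \code{"Normal"}
#' (no distortion) and IBD grades \code{"I"} (mild), \code{"II"} (moderate),
#' \code{"III"} (severe).
#'
#' @return Character vector of the four grade labels, in severity order.
#' @examples gradeLevels()
#' @export
gradeLevels <- function() c("Normal", "I", "II", "III")

#' @title BiopsyImage: a grayscale microscopy field
#'
#' @description Pixel grid of a single well-oriented mucosa field, with an
#' optional reference grade label and a free-text source identifier.
#' Intensities are stored as a numeric matrix on the 0--255 scale, indexed
#' \code{[row, column] = [y + 1, x + 1]} with x rightward and y downward
#' (0-based pixel coordinates in all boundary data).
#'
#' @slot pixels numeric matrix of intensities (0--255).
#' @slot grade character; one of \code{gradeLevels()} or \code{NA}.
#' @slot sourceId character; provenance label.
#' @exportClass BiopsyImage
setClass("BiopsyImage",
  representation(pixels = "matrix", grade = "character", sourceId = "character"),
  prototype(grade = NA_character_, sourceId = ""),
  validity = function(object) {
    if (length(object@pixels) == 0L) return("empty pixel grid")
    if (!all(is.finite(object@pixels))) return("non-finite intensities")
    if (!is.na(object@grade) && !object@grade %in% gradeLevels())
      return("grade must be one of gradeLevels() or NA")
    TRUE
  })

#' Construct a BiopsyImage
#'
#' @param pixels numeric matrix of intensities (0--255), rows = y, cols = x.
#' @param grade optional grade label (one of \code{gradeLevels()}).
#' @param sourceId provenance string.
#' @return A \linkS4class{BiopsyImage}.
#' @export
BiopsyImage <- function(pixels, grade = NA_character_, sourceId = "") {
  new("BiopsyImage", pixels = pixels, grade = as.character(grade),
      sourceId = sourceId)
}

#' @title Boundary: an ordered 2-D point sequence
#'
#' @description Ordered vertices in 0-based pixel coordinates (columns x, y).
#' Closed boundaries describe crypt outlines; the muscularis edge is stored
#' open. Closed crypt boundaries are oriented counter-clockwise in image
#' coordinates (y downward).
#'
#' @slot vertices two-column numeric matrix (x, y).
#' @slot closed logical flag.
#' @exportClass Boundary
setClass("Boundary",
  representation(vertices = "matrix", closed = "logical"),
  validity = function(object) {
    V <- object@vertices
    if (ncol(V) != 2L) return("vertices must have two columns (x, y)")
    if (object@closed && nrow(V) < 3L) return("closed boundary needs >= 3 vertices")
    if (nrow(V) >= 2L) {
      d <- rowSums(abs(diff(V)))
      if (any(d == 0)) return("repeated consecutive vertices")
    }
    TRUE
  })

#' Construct a Boundary
#'
#' @param vertices two-column matrix of (x, y) pixel coordinates.
#' @param closed logical; \code{TRUE} for crypt outlines.
#' @return A \linkS4class{Boundary}.
#' @export
Boundary <- function(vertices, closed = TRUE) {
  colnames(vertices) <- c("x", "y")
  new("Boundary", vertices = vertices, closed = closed)
}

#' @title ContourSet: segmented crypts and muscularis edge
#'
#' @description The output of segmentation: a list of closed crypt
#' \linkS4class{Boundary} objects and the open muscularis polyline (or
#' \code{NULL} when no muscularis band was found).
#'
#' @slot crypts list of closed \linkS4class{Boundary} objects.
#' @slot muscularis open \linkS4class{Boundary} or \code{NULL}.
#' @exportClass ContourSet
setClass("ContourSet",
  representation(crypts = "list", muscularis = "ANY"),
  prototype(muscularis = NULL),
  validity = function(object) {
    for (b in object@crypts) {
      if (!is(b, "Boundary")) return("crypts must contain Boundary objects")
      if (!b@closed) return("crypt boundaries must be closed")
    }
    if (!is.null(object@muscularis) && !is(object@muscularis, "Boundary"))
      return("muscularis must be a Boundary or NULL")
    if (length(object@crypts) >= 2L) {
      ctr <- t(vapply(object@crypts, function(b) polygonCentroid(b@vertices),
                      numeric(2)))
      for (i in seq_along(object@crypts)) {
        others <- setdiff(seq_along(object@crypts), i)
        V <- object@crypts[[i]]@vertices
        if (any(pointInPolygon(ctr[others, 1L], ctr[others, 2L], V)))
          return("nested crypt boundaries")
      }
    }
    TRUE
  })

#' Construct a ContourSet
#'
#' @param crypts list of closed \linkS4class{Boundary} objects.
#' @param muscularis open \linkS4class{Boundary} or \code{NULL}.
#' @return A \linkS4class{ContourSet}.
#' @export
ContourSet <- function(crypts = list(), muscularis = NULL) {
  new("ContourSet", crypts = crypts, muscularis = muscularis)
}

#' @title GradeParams: generator parameters for one grade
#'
#' @description Parameters controlling the synthetic-image generator for one
#' severity grade. The defaults encode the histological ordering of
#' architectural distortion: boundary distortion, basal gap and spacing
#' irregularity increase with grade while crypt density decreases.
#'
#' @slot grade character grade label.
#' @slot boundaryDistortion dimensionless harmonic perturbation amplitude in [0,1].
#' @slot cryptCountRange integer interval (min, max) of crypts per field.
#' @slot spacingJitter fraction of nominal spacing used as placement jitter.
#' @slot basalGap nominal crypt-base to muscularis distance, pixels.
#' @slot gapJitter fraction of basalGap used as per-crypt jitter.
#' @exportClass GradeParams
setClass("GradeParams",
  representation(grade = "character", boundaryDistortion = "numeric",
                 cryptCountRange = "integer", spacingJitter = "numeric",
                 basalGap = "numeric", gapJitter = "numeric"),
  validity = function(object) {
    if (!object@grade %in% gradeLevels()) return("unknown grade")
    if (object@boundaryDistortion < 0 || object@boundaryDistortion > 1)
      return("boundaryDistortion must be in [0, 1]")
    if (length(object@cryptCountRange) != 2L ||
        object@cryptCountRange[1L] > object@cryptCountRange[2L] ||
        object@cryptCountRange[1L] < 1L)
      return("cryptCountRange must be a positive (min, max) interval")
    if (object@basalGap <= 0) return("basalGap must be positive")
    if (object@spacingJitter < 0 || object@gapJitter < 0)
      return("jitters must be non-negative")
    TRUE
  })

#' Default generator parameters for a grade
#'
#' Per-grade defaults: boundary distortion (0.03, 0.15, 0.35, 0.60), crypt
#' count ranges (18--24, 12--18, 8--12, 4--8), basal gaps (15, 25, 40, 60) px
#' and spacing jitters (0.10, 0.18, 0.28, 0.40) for Normal through grade III.
#'
#' @param grade one of \code{gradeLevels()}.
#' @param boundaryDistortion,cryptCountRange,spacingJitter,basalGap,gapJitter
#'   overrides for individual fields.
#' @return A \linkS4class{GradeParams} object.
#' @examples gradeParams("II")
#' @export
gradeParams <- function(grade,
                        boundaryDistortion = NULL, cryptCountRange = NULL,
                        spacingJitter = NULL, basalGap = NULL, gapJitter = NULL) {
  grade <- match.arg(grade, gradeLevels())
  i <- match(grade, gradeLevels())
  def <- list(
    boundaryDistortion = c(0.03, 0.15, 0.35, 0.60)[i],
    cryptCountRange = rbind(c(18L, 24L), c(12L, 18L), c(8L, 12L), c(4L, 8L))[i, ],
    spacingJitter = c(0.10, 0.18, 0.28, 0.40)[i],
    basalGap = c(15, 25, 40, 60)[i],
    gapJitter = 0.20)
  new("GradeParams", grade = grade,
      boundaryDistortion = boundaryDistortion %||% def$boundaryDistortion,
      cryptCountRange = as.integer(cryptCountRange %||% def$cryptCountRange),
      spacingJitter = spacingJitter %||% def$spacingJitter,
      basalGap = basalGap %||% def$basalGap,
      gapJitter = gapJitter %||% def$gapJitter)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @title GroundTruth: exact primitives behind a synthetic image
#'
#' @description Every primitive the generator placed: closed crypt boundaries,
#' their (shoelace) centroids, the muscularis top-edge polyline spanning the
#' full image width, and the grade label.
#'
#' @slot boundaries list of closed \linkS4class{Boundary} objects.
#' @slot centroids two-column matrix, one row per boundary.
#' @slot muscularis two-column matrix, open polyline across the image width.
#' @slot grade character grade label.
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(boundaries = "list", centroids = "matrix",
                 muscularis = "matrix", grade = "character"),
  validity = function(object) {
    if (length(object@boundaries) != nrow(object@centroids))
      return("one centroid per boundary required")
    for (i in seq_along(object@boundaries)) {
      V <- object@boundaries[[i]]@vertices
      if (!pointInPolygon(object@centroids[i, 1L], object@centroids[i, 2L], V))
        return("centroid outside its boundary")
    }
    TRUE
  })

#' @title SnakeConfig: active-contour energy weights and controls
#'
#' @description Parameters of the greedy snake: weights of the internal
#' continuity (tension) and curvature energies, the image (edge) energy and
#' the constraint (containment) energy, plus iteration controls.
#'
#' @slot alpha continuity (tension) weight.
#' @slot beta curvature weight.
#' @slot gamma image-energy weight.
#' @slot kappa constraint-energy weight.
#' @slot maxIters iteration cap.
#' @slot moveTol convergence threshold on the per-sweep max vertex move, px.
#' @slot nVertices number of snake vertices.
#' @exportClass SnakeConfig
setClass("SnakeConfig",
  representation(alpha = "numeric", beta = "numeric", gamma = "numeric",
                 kappa = "numeric", maxIters = "integer", moveTol = "numeric",
                 nVertices = "integer"),
  validity = function(object) {
    w <- c(object@alpha, object@beta, object@gamma, object@kappa)
    if (any(w < 0)) return("energy weights must be non-negative")
    if (object@nVertices < 8L) return("nVertices must be >= 8")
    if (object@maxIters < 1L) return("maxIters must be >= 1")
    TRUE
  })

#' Construct a SnakeConfig
#'
#' Defaults are standard greedy-snake settings: alpha 0.4, beta 0.2, gamma 1.0,
#' kappa 0.1, 64 vertices, move tolerance 0.5 px, at most 500 sweeps.
#'
#' @param alpha,beta,gamma,kappa energy weights (continuity, curvature, image,
#'   constraint), all non-negative.
#' @param maxIters iteration cap.
#' @param moveTol convergence threshold in pixels.
#' @param nVertices number of snake vertices (>= 8).
#' @return A \linkS4class{SnakeConfig}.
#' @export
snakeConfig <- function(alpha = 0.4, beta = 0.2, gamma = 1.0, kappa = 0.1,
                        maxIters = 500L, moveTol = 0.5, nVertices = 64L) {
  new("SnakeConfig", alpha = alpha, beta = beta, gamma = gamma, kappa = kappa,
      maxIters = as.integer(maxIters), moveTol = moveTol,
      nVertices = as.integer(nVertices))
}

#' @title PNNModel: a trained probabilistic neural network
#'
#' @description Stored (min-max scaled) training patterns grouped by grade,
#' the Gaussian-kernel smoothing width, class prior probabilities and
#' misclassification losses, and the feature scaler fitted on the training
#' set. A PNN has no iterative weight fitting: the hidden layer holds one
#' node per training pattern.
#'
#' @slot patterns numeric matrix, one scaled training pattern per row.
#' @slot labels factor of grade labels, levels = \code{gradeLevels()}.
#' @slot sigma positive smoothing width of the Gaussian kernel.
#' @slot priors per-class prior probabilities (sum to 1).
#' @slot losses per-class positive misclassification losses.
#' @slot scalerMin,scalerMax per-feature training extremes for min-max scaling.
#' @slot featureNames feature column names.
#' @slot version serialization format version.
#' @exportClass PNNModel
setClass("PNNModel",
  representation(patterns = "matrix", labels = "factor", sigma = "numeric",
                 priors = "numeric", losses = "numeric",
                 scalerMin = "numeric", scalerMax = "numeric",
                 featureNames = "character", version = "character"),
  validity = function(object) {
    if (object@sigma <= 0) return("sigma must be positive")
    if (nrow(object@patterns) != length(object@labels))
      return("one label per pattern required")
    if (length(object@priors) != 4L || any(object@priors < 0) ||
        abs(sum(object@priors) - 1) > 1e-8)
      return("priors must be 4 non-negative values summing to 1")
    if (length(object@losses) != 4L || any(object@losses <= 0))
      return("losses must be 4 positive values")
    if (nlevels(droplevels(object@labels)) < 1L)
      return("at least one represented class required")
    TRUE
  })

#' @title EvaluationReport: confusion matrix and precision/recall
#'
#' @description A 4x4 confusion matrix (rows = reference grade, columns =
#' system classification) with per-class precision (correct over all cases
#' classified into the class), per-class recall (correct over all true cases
#' of the class) and overall precision (trace over total). Classes with a
#' zero denominator carry \code{NA}.
#'
#' @slot confusion 4x4 integer matrix.
#' @slot precision,recall named per-class values in [0, 1] (or NA).
#' @slot overallPrecision trace / total.
#' @slot nCases total case count.
#' @exportClass EvaluationReport
setClass("EvaluationReport",
  representation(confusion = "matrix", precision = "numeric",
                 recall = "numeric", overallPrecision = "numeric",
                 nCases = "integer"),
  validity = function(object) {
    if (any(object@confusion < 0)) return("negative confusion counts")
    if (!identical(dim(object@confusion), c(4L, 4L)))
      return("confusion must be 4x4")
    TRUE
  })
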