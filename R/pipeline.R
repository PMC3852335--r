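# End-to-end orchestration: image -> 11 features -> grade.

#' Pipeline configuration
#'
#' Bundles all stage parameters: segmentation (snake configuration, area and
#' solidity filters, polarity, median/closing radii), the number of angular
#' samples K for the shape descriptors, and the normalization readings of
#' the two distance features.
#'
#' @param snake a \linkS4class{SnakeConfig}.
#' @param K angular samples for the radial signature.
#' @param minArea,maxArea,minSolidity crypt filters (see
#'   \code{\link{segmentBiopsy}}).
#' @param medianRadius,closingRadius preprocessing radii (see
#'   \code{\link{preprocessImage}}).
#' @param darkObjects polarity flag.
#' @param spacingDenominator \code{"mst"} or \code{"pairwise"} (see
#'   \code{\link{cryptSpacingFeature}}).
#' @param distanceMode \code{"scaled"} or \code{"ratio"} (see
#'   \code{\link{muscularisDistanceFeature}}).
#' @return A named list of class \code{"pipelineConfig"}.
#' @export
pipelineConfig <- function(snake = snakeConfig(), K = 64L,
                           minArea = 300, maxArea = 15000, minSolidity = 0.35,
                           medianRadius = 2L, closingRadius = 45L,
                           darkObjects = TRUE,
                           spacingDenominator = c("mst", "pairwise"),
                           distanceMode = c("scaled", "ratio")) {
  structure(list(snake = snake, K = as.integer(K), minArea = minArea,
                 maxArea = maxArea, minSolidity = minSolidity,
                 medianRadius = as.integer(medianRadius),
                 closingRadius = as.integer(closingRadius),
                 darkObjects = darkObjects,
                 spacingDenominator = match.arg(spacingDenominator),
                 distanceMode = match.arg(distanceMode)),
            class = "pipelineConfig")
}

# 11 features from an already-segmented contour set.
featuresFromContours <- function(contours, imageDim, config = pipelineConfig()) {
  diag <- sqrt(sum(imageDim^2))
  cl <- crypts(contours)
  qc <- list(nCrypts = length(cl), hardWarning = FALSE)
  if (length(cl) == 0L) {
    f <- stats::setNames(c(numeric(9L), 1.0, 1.0), featureNamesDefault())
    qc$hardWarning <- TRUE
    qc$nDegenerate <- 0L
    qc$muscularisFound <- !is.null(muscularis(contours))
    qc$sparse <- TRUE; qc$distanceSentinel <- TRUE
    return(list(features = f, qc = qc))
  }
  fd <- imageShapeFeatures(contours, K = config$K)
  ctrs <- t(vapply(cl, centroidFromBoundary, numeric(3)))
  sp <- cryptSpacingFeature(ctrs[, c("x", "y"), drop = FALSE],
                            denominator = config$spacingDenominator)
  md <- muscularisDistanceFeature(muscularis(contours), cl, imageDiag = diag,
                                  mode = config$distanceMode)
  f <- stats::setNames(c(as.numeric(fd), as.numeric(sp), as.numeric(md)),
                       featureNamesDefault())
  qc$nDegenerate <- attr(fd, "nDegenerate")
  qc$allDegenerate <- attr(fd, "allDegenerate")
  qc$muscularisFound <- !is.null(muscularis(contours))
  qc$sparse <- isTRUE(attr(sp, "sparse"))
  qc$distanceSentinel <- isTRUE(attr(md, "sentinel"))
  list(features = f, qc = qc)
}

#' Extract the 11-feature vector of one image
#'
#' Segments the image and computes the full feature vector
#' \code{[fd1..fd9, mst_spacing, musc_distance]}. Sentinel and degeneracy
#' flags from every stage are propagated into the QC record; an image with
#' zero detected crypts yields the all-sentinel vector and a hard QC
#' warning.
#'
#' @param image a \linkS4class{BiopsyImage}.
#' @param background optional paired background image.
#' @param config a \code{\link{pipelineConfig}}.
#' @return List with \code{features} (named numeric, length 11), \code{qc}
#'   (list of flags) and \code{contours} (the \linkS4class{ContourSet}).
#' @export
extractFeatures <- function(image, background = NULL,
                            config = pipelineConfig()) {
  stopifnot(is(image, "BiopsyImage"))
  contours <- segmentBiopsy(image, background, config = config$snake,
                            minArea = config$minArea, maxArea = config$maxArea,
                            minSolidity = config$minSolidity,
                            darkObjects = config$darkObjects)
  out <- featuresFromContours(contours, dim(pixels(image)), config)
  out$contours <- contours
  out
}

#' Stratified train/test split
#'
#' Splits case indices by grade: per-class training sizes are
#' \code{round(fraction * n_class)} adjusted by largest remainder so the
#' total equals \code{round(fraction * n)}. A class with fewer than 2 cases
#' goes entirely to training with a warning. Deterministic under
#' \code{seed}.
#'
#' @param labels grade labels, one per case.
#' @param trainFraction fraction of cases for training, in (0, 1).
#' @param seed integer seed.
#' @return List with integer index vectors \code{train} and \code{test}.
#' @export
splitDataset <- function(labels, trainFraction = 2 / 3, seed = 1L) {
  stopifnot(trainFraction > 0, trainFraction < 1)
  labels <- factor(as.character(labels), levels = gradeLevels())
  n <- length(labels)
  counts <- table(labels)
  small <- names(counts)[counts > 0 & counts < 2L]
  if (length(small))
    warning("class(es) with < 2 cases assigned entirely to training: ",
            paste(small, collapse = ", "))
  eligible <- names(counts)[counts >= 2L]
  base <- integer(0)
  if (length(eligible)) {
    target <- min(sum(counts[eligible]),
                  max(0, round(trainFraction * n) - sum(counts[small])))
    exact <- trainFraction * counts[eligible]
    base <- floor(exact)
    rem <- target - sum(base)
    if (rem > 0) {
      ord <- order(exact - base, decreasing = TRUE)
      base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1L
    } else if (rem < 0) {
      ord <- order(exact - base)
      take <- ord[base[ord] > 0][seq_len(-rem)]
      base[take] <- base[take] - 1L
    }
  }
  train <- integer(0)
  withSeed(seed, {
    for (g in names(counts)[counts > 0]) {
      idx <- which(labels == g)
      k <- if (g %in% small) length(idx) else base[g]
      sel <- if (k >= length(idx)) idx else sample(idx, k)
      train <- c(train, sel)
    }
  })
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Grade one biopsy image end to end
#'
#' Runs \code{\link{extractFeatures}} then \code{\link{classifyPNN}}. An
#' image whose extraction raises the hard QC warning (zero crypts) is
#' reported with status \code{"unreadable"} and grade \code{NA}, never a
#' silent grade.
#'
#' @param image a \linkS4class{BiopsyImage}.
#' @param model a trained \linkS4class{PNNModel}.
#' @param config a \code{\link{pipelineConfig}}.
#' @param background optional paired background image.
#' @return List with \code{grade} (character or NA), \code{status}
#'   (\code{"ok"} or \code{"unreadable"}), \code{features}, \code{scores}
#'   and \code{qc} (including the model version).
#' @export
gradeBiopsy <- function(image, model, config = pipelineConfig(),
                        background = NULL) {
  stopifnot(is(model, "PNNModel"))
  ex <- extractFeatures(image, background, config)
  qc <- ex$qc
  qc$modelVersion <- model@version
  qc$sourceId <- sourceId(image)
  if (isTRUE(ex$qc$hardWarning))
    return(list(grade = NA_character_, status = "unreadable",
                features = ex$features, scores = NULL, qc = qc))
  cls <- classifyPNN(model, ex$features)
  list(grade = cls$grade, status = "ok", features = ex$features,
       scores = cls$scores, qc = qc)
}

#' Feature table of a synthetic cohort
#'
#' Applies \code{\link{extractFeatures}} to every rendered image of a cohort
#' from \code{\link{generateCohort}} and assembles the per-image feature
#' rows with their reference grades and QC counts.
#'
#' @param cohort list from \code{\link{generateCohort}} (rendered).
#' @param config a \code{\link{pipelineConfig}}.
#' @param useBackground use each image's paired background for
#'   preprocessing.
#' @return data.frame with columns \code{source_id}, \code{grade},
#'   \code{fd1..fd9}, \code{mst_spacing}, \code{musc_distance},
#'   \code{n_crypts}, \code{n_degenerate}.
#' @export
cohortFeatures <- function(cohort, config = pipelineConfig(),
                           useBackground = TRUE) {
  rows <- lapply(cohort, function(sim) {
    stopifnot(!is.null(sim$image))
    bg <- if (useBackground) sim$background else NULL
    ex <- extractFeatures(sim$image, bg, config)
    data.frame(source_id = sourceId(sim$image),
               grade = imageGrade(sim$truth),
               as.list(ex$features),
               n_crypts = ex$qc$nCrypts,
               n_degenerate = ex$qc$nDegenerate %||% 0L)
  })
  do.call(rbind, rows)
}
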