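# Preprocessing and crypt/muscularis localization.
#
# Crypts are assumed darker than the surrounding stroma (lumina); the
# muscularis mucosa is modeled as the dark band along the bottom of a
# well-oriented field. All coordinates are 0-based pixels, x rightward,
# y downward.

#' Clean a biopsy image
#'
#' Subtracts illumination (an explicit paired background image when given,
#' otherwise a grayscale-closing estimate with a structuring element much
#' larger than a crypt), clips and rescales the result to the full 0--255
#' range, then applies a median filter. Closing, not opening, is the
#' object-removing background estimator for dark objects on a light
#' background; the estimate switches to opening when \code{darkObjects}
#' is \code{FALSE}.
#'
#' @param image a \linkS4class{BiopsyImage}.
#' @param background optional paired \linkS4class{BiopsyImage} of identical
#'   size (e.g. a blank-slide exposure).
#' @param medianRadius median filter radius in pixels.
#' @param closingRadius structuring-element radius for the background
#'   estimate (pixels); should be well above the crypt radius.
#' @param darkObjects logical; \code{TRUE} (default) when crypts are darker
#'   than stroma.
#' @return A cleaned \linkS4class{BiopsyImage}.
#' @export
preprocessImage <- function(image, background = NULL, medianRadius = 2L,
                            closingRadius = 45L, darkObjects = TRUE) {
  stopifnot(is(image, "BiopsyImage"))
  m <- pixels(image)
  if (!is.null(background)) {
    stopifnot(is(background, "BiopsyImage"))
    if (!identical(dim(pixels(background)), dim(m)))
      stop("background dimensions do not match the image")
    bg <- pixels(background)
  } else {
    sz <- 2L * as.integer(closingRadius) + 1L
    brush <- EBImage::makeBrush(sz, shape = "disc")
    bg <- if (darkObjects) EBImage::closing(m / 255, brush) * 255
          else EBImage::opening(m / 255, brush) * 255
  }
  d <- m - bg
  rng <- range(d)
  out <- if (rng[2L] > rng[1L]) (d - rng[1L]) / (rng[2L] - rng[1L]) * 255
         else matrix(0, nrow = nrow(m), ncol = ncol(m))
  if (medianRadius >= 1L)
    out <- EBImage::medianFilter(out / 255, as.integer(medianRadius)) * 255
  BiopsyImage(out, grade = image@grade, sourceId = image@sourceId)
}

#' Initial snake contours from thresholded components
#'
#' Otsu-thresholds the cleaned image (dark side for the default polarity),
#' fills holes, labels connected components, drops components touching the
#' bottom border (muscularis band) and outside the area window, and returns
#' one initial contour per surviving component: its convex hull dilated
#' outward about its centroid and resampled to \code{nVertices} points.
#'
#' @param clean a cleaned \linkS4class{BiopsyImage}.
#' @param minArea,maxArea component area window in squared pixels.
#' @param nVertices vertices per initial contour.
#' @param dilate outward dilation factor applied to the hull.
#' @param darkObjects polarity flag, as in \code{\link{preprocessImage}}.
#' @return List of closed \linkS4class{Boundary} objects (possibly empty).
#' @export
initializeContours <- function(clean, minArea = 300, maxArea = 15000,
                               nVertices = 64L, dilate = 1.12,
                               darkObjects = TRUE) {
  stopifnot(is(clean, "BiopsyImage"), minArea < maxArea)
  m <- pixels(clean) / 255
  if (max(m) == min(m)) return(list())
  thr <- EBImage::otsu(m, range = range(m))
  bin <- if (darkObjects) m < thr else m > thr
  bin <- EBImage::fillHull(bin)
  lab <- EBImage::bwlabel(bin)
  nlab <- max(lab)
  if (nlab == 0L) return(list())
  h <- nrow(lab)
  out <- list()
  for (l in seq_len(nlab)) {
    idx <- which(lab == l)
    area <- length(idx)
    if (area < minArea || area > maxArea) next
    ry <- ((idx - 1L) %% h) + 1L
    if (any(ry == h)) next  # touches the bottom border: muscularis band
    rx <- ((idx - 1L) %/% h) + 1L
    pts <- cbind(x = rx - 1L, y = ry - 1L)
    hull <- pts[grDevices::chull(pts), , drop = FALSE]
    if (nrow(hull) < 3L) next
    ctr <- colMeans(pts)
    hull <- sweep(sweep(hull, 2L, ctr) * dilate, 2L, ctr, `+`)
    V <- resamplePolyline(hull, nVertices, closed = TRUE)
    V[, 1L] <- pmin(pmax(V[, 1L], 0), ncol(lab) - 1L)
    V[, 2L] <- pmin(pmax(V[, 2L], 0), nrow(lab) - 1L)
    out[[length(out) + 1L]] <- Boundary(V, closed = TRUE)
  }
  out
}

# Upper edge of the lowest dark horizontal band, as an open polyline.
# Returns NULL when no dark component touching the bottom border spans a
# reasonable fraction of the image width.
extractMuscularis <- function(clean, darkObjects = TRUE, minWidthFrac = 0.6,
                              step = 2L) {
  m <- pixels(clean) / 255
  if (max(m) == min(m)) return(NULL)
  thr <- EBImage::otsu(m, range = range(m))
  bin <- if (darkObjects) m < thr else m > thr
  lab <- EBImage::bwlabel(bin)
  h <- nrow(lab); w <- ncol(lab)
  bottom <- unique(lab[h, ])
  bottom <- bottom[bottom > 0]
  if (length(bottom) == 0L) return(NULL)
  sizes <- vapply(bottom, function(l) sum(lab == l), numeric(1))
  l <- bottom[which.max(sizes)]
  comp <- lab == l
  ytop <- apply(comp, 2L, function(col) {
    i <- which(col)
    if (length(i)) min(i) else NA_integer_
  })
  if (mean(!is.na(ytop)) < minWidthFrac) return(NULL)
  # fill gaps by interpolation so the polyline spans the full width
  xs <- seq_len(w)
  ok <- !is.na(ytop)
  ytop <- stats::approx(xs[ok], ytop[ok], xout = xs, rule = 2)$y
  sel <- unique(c(seq(1L, w, by = step), w))
  Boundary(cbind(x = xs[sel] - 1L, y = ytop[sel] - 1L), closed = FALSE)
}

#' Segment a biopsy image into crypts and the muscularis edge
#'
#' Runs \code{\link{preprocessImage}}, \code{\link{initializeContours}} and
#' \code{\link{evolveSnake}} for each initial contour, keeps converged snakes
#' passing area and solidity filters, and extracts the muscularis as the
#' upper edge of the largest dark component touching the bottom border. The
#' procedure is fully deterministic.
#'
#' @param image a \linkS4class{BiopsyImage}.
#' @param background optional paired background image.
#' @param config a \linkS4class{SnakeConfig}.
#' @param minArea,maxArea component area window (squared pixels).
#' @param minSolidity minimum area/convex-hull-area ratio for a kept crypt.
#' @param darkObjects polarity flag.
#' @return A \linkS4class{ContourSet}; \code{muscularis} is \code{NULL} when
#'   no band is found.
#' @export
segmentBiopsy <- function(image, background = NULL, config = snakeConfig(),
                          minArea = 300, maxArea = 15000, minSolidity = 0.35,
                          darkObjects = TRUE) {
  clean <- preprocessImage(image, background, darkObjects = darkObjects)
  inits <- initializeContours(clean, minArea = minArea, maxArea = maxArea,
                              nVertices = config@nVertices,
                              darkObjects = darkObjects)
  eimg <- snakeEnergyImage(clean)
  kept <- list()
  for (b in inits) {
    s <- evolveSnake(b, clean, config, energyImage = eimg)
    if (isTRUE(attr(s, "failed"))) next
    V <- vertices(s)
    a <- abs(polygonArea(V))
    if (a < minArea || a > maxArea) next
    hullA <- abs(polygonArea(V[grDevices::chull(V), , drop = FALSE]))
    if (hullA <= 0 || a / hullA < minSolidity) next
    kept[[length(kept) + 1L]] <- s
  }
  # drop nested contours (keep the larger of a nested pair)
  if (length(kept) >= 2L) {
    ctr <- t(vapply(kept, function(b) polygonCentroid(vertices(b)), numeric(2)))
    areas <- vapply(kept, function(b) abs(polygonArea(vertices(b))), numeric(1))
    drop <- logical(length(kept))
    for (i in seq_along(kept)) {
      for (j in seq_along(kept)) {
        if (i == j || drop[j]) next
        if (pointInPolygon(ctr[i, 1L], ctr[i, 2L], vertices(kept[[j]])) &&
            areas[i] <= areas[j])
          drop[i] <- TRUE
      }
    }
    kept <- kept[!drop]
  }
  ContourSet(crypts = kept,
             muscularis = extractMuscularis(clean, darkObjects = darkObjects))
}
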