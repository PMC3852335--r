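# Synthetic mucosa image generator with exact ground truth.
#
# Emulates a well-oriented 10x field: dark star-shaped crypt lumina over a
# lighter stroma, a dark muscularis band along the bottom edge, additive
# Gaussian noise and a smooth multiplicative illumination field. Grade
# severity enters through the GradeParams defaults: boundary distortion,
# basal gap and spacing irregularity increase with grade, crypt density
# decreases.

#' Generate one star-shaped crypt boundary
#'
#' The boundary is a harmonic perturbation of a circle:
#' \deqn{r(\theta) = R\,(1 + d \sum_h c_h \cos(h\theta + \phi_h))}
#' with coefficients drawn from the seeded generator and rescaled so the
#' total perturbation amplitude is at most 0.8, guaranteeing \eqn{r > 0} and
#' a simple (non-self-intersecting), star-shaped polygon. Harmonics start at
#' order 2: a first-order radial harmonic is (to first order) a translation
#' of the shape rather than a deformation, so it carries no shape
#' information about the centroid-parameterized outline.
#'
#' @param baseRadius circle radius R in pixels (> 0).
#' @param distortion perturbation amplitude d in [0, 1].
#' @param nHarmonics number of harmonic components (orders 2..nHarmonics+1).
#' @param seed integer seed; identical seeds give bitwise-identical polygons.
#' @param nPoints number of polygon vertices.
#' @return A closed \linkS4class{Boundary} centered at the origin, with the
#'   drawn harmonic coefficients attached as attribute \code{"harmonics"}
#'   (list with elements \code{baseRadius}, \code{distortion}, \code{h},
#'   \code{c}, \code{phi}).
#' @examples
#' b <- generateCryptBoundary(28, 0.35, seed = 1)
#' range(sqrt(rowSums(vertices(b)^2)))
#' @export
generateCryptBoundary <- function(baseRadius, distortion, nHarmonics = 5L,
                                  seed = 1L, nPoints = 128L) {
  if (baseRadius <= 0) stop("baseRadius must be positive")
  if (distortion < 0 || distortion > 1) stop("distortion must be in [0, 1]")
  h <- 2L:(nHarmonics + 1L)
  co <- withSeed(seed, {
    c0 <- stats::runif(nHarmonics, 0.3, 1)
    list(c = 0.8 * c0 / sum(c0), phi = stats::runif(nHarmonics, 0, 2 * pi))
  })
  theta <- 2 * pi * (0:(nPoints - 1L)) / nPoints
  r <- evalRadial(theta, baseRadius, distortion, h, co$c, co$phi)
  b <- Boundary(cbind(r * cos(theta), r * sin(theta)), closed = TRUE)
  attr(b, "harmonics") <- list(baseRadius = baseRadius, distortion = distortion,
                               h = h, c = co$c, phi = co$phi)
  b
}

# r(theta) for a harmonic crypt profile; vectorized over theta.
evalRadial <- function(theta, baseRadius, distortion, h, c, phi) {
  pert <- colSums(c * cos(outer(h, theta) + phi))
  baseRadius * (1 + distortion * pert)
}

#' Generate one synthetic biopsy image with ground truth
#'
#' Places crypts on a jittered grid above a dark muscularis band, with the
#' bottom-row crypt bases at the grade's nominal basal gap from the band's
#' top edge. Rendering adds a Gaussian blur (edge softness), a smooth
#' low-order polynomial illumination field of amplitude +/-10 percent of
#' the stroma intensity (additive, so a paired background exposure cancels
#' it exactly under subtraction), and Gaussian noise of 5 gray levels. Crypts never overlap the
#' muscularis band; crypts that cannot be placed without overlap after
#' repeated retries are dropped (the ground truth records what was placed).
#'
#' @param params a \linkS4class{GradeParams} object.
#' @param width,height canvas size in pixels.
#' @param seed integer seed; identical seeds give bitwise-identical output.
#' @param render if \code{FALSE}, skip pixel rendering (ground truth only;
#'   the returned \code{image} is \code{NULL}). The ground truth is identical
#'   either way.
#' @return List with elements \code{image} (\linkS4class{BiopsyImage} or
#'   \code{NULL}), \code{truth} (\linkS4class{GroundTruth}) and
#'   \code{background} (\linkS4class{BiopsyImage} of the blank-slide
#'   illumination field, or \code{NULL} when not rendered).
#' @examples
#' sim <- generateBiopsyImage(gradeParams("Normal"), 400, 300, seed = 7)
#' length(cryptBoundaries(sim$truth))
#' @export
generateBiopsyImage <- function(params, width = 800L, height = 600L, seed = 1L,
                                render = TRUE) {
  stopifnot(is(params, "GradeParams"))
  width <- as.integer(width); height <- as.integer(height)
  R0 <- 0.035 * width
  if (height < params@basalGap + 4 * R0)
    stop("canvas too small to host the requested crypt layout")

  withSeed(seed, {
    # muscularis band: gently wavy top edge along the bottom of the canvas
    bandH <- round(0.07 * height)
    wavePhase <- stats::runif(1, 0, 2 * pi)
    waveFreq <- stats::runif(1, 1.0, 2.0)
    xAll <- 0:(width - 1L)
    yBand <- height - bandH + 4 * sin(2 * pi * waveFreq * xAll / width + wavePhase)
    yTopMin <- min(yBand)

    # illumination field coefficients (drawn before placement-independent use)
    illumCoef <- stats::runif(5, -1, 1)

    n <- sample(params@cryptCountRange[1L]:params@cryptCountRange[2L], 1L)
    havail <- yTopMin - params@basalGap - 2.2 * R0
    sTarget <- sqrt(width * max(havail, 2.2 * R0) / n)
    nCols <- max(1L, as.integer(round(width / sTarget)))
    colSp <- width / nCols
    nRows <- as.integer(ceiling(n / nCols))
    rowSp <- min(sTarget, havail / max(1L, nRows - 1L) )
    if (!is.finite(rowSp) || nRows == 1L) rowSp <- sTarget

    placed <- list(); centers <- NULL
    for (k in seq_len(n)) {
      row <- ((k - 1L) %/% nCols) + 1L
      col <- ((k - 1L) %% nCols) + 1L
      Rk <- R0 * stats::runif(1, 0.85, 1.15)
      gapK <- params@basalGap * (1 + params@gapJitter * stats::runif(1, -1, 1))
      bnd <- generateCryptBoundary(Rk, params@boundaryDistortion,
                                   seed = childSeed(seed, k))
      V <- vertices(bnd)
      maxVy <- max(V[, 2L]); rmax <- max(sqrt(rowSums(V^2)))
      ok <- FALSE
      for (try in 1:20) {
        cx <- (col - 0.5) * colSp +
          params@spacingJitter * colSp * stats::runif(1, -1, 1)
        cx <- min(max(cx, rmax + 3), width - rmax - 3)
        if (row == 1L) {
          cy <- yBand[round(cx) + 1L] - gapK - maxVy
        } else {
          cy <- yTopMin - params@basalGap - maxVy - (row - 1L) * rowSp +
            params@spacingJitter * rowSp * stats::runif(1, -1, 1)
        }
        if (cy - rmax < 3) next
        if (cy + rmax > min(yBand[pmax(1, pmin(width, round(cx) + (-50:50)))]) - 2)
          next
        if (!is.null(centers)) {
          dd <- sqrt((centers[, 1L] - cx)^2 + (centers[, 2L] - cy)^2)
          if (any(dd < rmax + centers[, 3L] + 6)) next
        }
        ok <- TRUE
        break
      }
      if (!ok) next  # unplaceable after retries: reduce the count
      centers <- rbind(centers, c(cx, cy, rmax))
      hh <- attr(bnd, "harmonics")
      hh$center <- c(cx, cy)
      bb <- Boundary(cbind(V[, 1L] + cx, V[, 2L] + cy), closed = TRUE)
      attr(bb, "harmonics") <- hh
      placed[[length(placed) + 1L]] <- bb
    }

    centroids <- if (length(placed))
      t(vapply(placed, function(b) polygonCentroid(vertices(b)), numeric(2)))
    else matrix(numeric(0), ncol = 2L)
    truth <- new("GroundTruth", boundaries = placed, centroids = centroids,
                 muscularis = cbind(x = xAll, y = yBand), grade = params@grade)

    if (!render)
      return(list(image = NULL, truth = truth, background = NULL))

    stromaI <- 185; lumenI <- 70; muscI <- 50; blankI <- 230
    base <- matrix(stromaI, nrow = height, ncol = width)
    for (x in xAll) {
      y0 <- max(1L, min(height, as.integer(ceiling(yBand[x + 1L])) + 1L))
      base[y0:height, x + 1L] <- muscI
    }
    for (b in placed) {
      hh <- attr(b, "harmonics")
      V <- vertices(b)
      xr <- max(0L, floor(min(V[, 1L]))):min(width - 1L, ceiling(max(V[, 1L])))
      yr <- max(0L, floor(min(V[, 2L]))):min(height - 1L, ceiling(max(V[, 2L])))
      px <- rep(xr, each = length(yr)); py <- rep(yr, times = length(xr))
      dx <- px - hh$center[1L]; dy <- py - hh$center[2L]
      th <- atan2(dy, dx)
      rth <- evalRadial(th, hh$baseRadius, hh$distortion, hh$h, hh$c, hh$phi)
      ins <- sqrt(dx^2 + dy^2) <= rth
      base[cbind(py[ins] + 1L, px[ins] + 1L)] <- lumenI
    }
    sm <- EBImage::gblur(base / 255, sigma = 1.2) * 255

    X <- matrix(rep(2 * xAll / (width - 1L) - 1, each = height),
                nrow = height)
    Y <- matrix(rep(2 * (0:(height - 1L)) / (height - 1L) - 1, times = width),
                nrow = height)
    field <- illumCoef[1L] * X + illumCoef[2L] * Y + illumCoef[3L] * X * Y +
      illumCoef[4L] * X^2 + illumCoef[5L] * Y^2
    field <- field / max(abs(field))
    illumAmp <- 0.1 * stromaI
    img <- sm + illumAmp * field
    img <- img + matrix(stats::rnorm(width * height, 0, 5), nrow = height)
    img <- pmin(pmax(img, 0), 255)

    bg <- pmin(pmax(blankI + illumAmp * field, 0), 255)
    list(image = BiopsyImage(img, grade = params@grade),
         truth = truth,
         background = BiopsyImage(bg, sourceId = "background"))
  })
}

#' Generate a balanced, seeded cohort of synthetic biopsy images
#'
#' Produces \code{4 * nPerGrade} images in grade-major order with per-image
#' seeds derived deterministically from \code{seed}.
#'
#' @param nPerGrade images per grade (>= 1).
#' @param seed master integer seed.
#' @param width,height canvas size passed to \code{\link{generateBiopsyImage}}.
#' @param render passed to \code{\link{generateBiopsyImage}}.
#' @return List of per-image results (see \code{\link{generateBiopsyImage}});
#'   each element additionally carries the grade's \code{params}.
#' @export
generateCohort <- function(nPerGrade, seed = 1L, width = 800L, height = 600L,
                           render = TRUE) {
  stopifnot(nPerGrade >= 1L)
  out <- vector("list", 4L * nPerGrade)
  k <- 0L
  for (g in gradeLevels()) {
    prm <- gradeParams(g)
    for (i in seq_len(nPerGrade)) {
      k <- k + 1L
      sim <- generateBiopsyImage(prm, width = width, height = height,
                                 seed = childSeed(seed, k), render = render)
      if (!is.null(sim$image))
        sim$image@sourceId <- sprintf("sim-%s-%03d", g, i)
      sim$params <- prm
      out[[k]] <- sim
    }
  }
  out
}
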