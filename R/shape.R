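# Fourier shape descriptors of crypt outlines.
#
# A closed crypt boundary is parameterized in polar form r(theta) about its
# centroid, sampled at K equally spaced angles (exact ray-polygon
# intersection, taking the maximum crossing so r stays single-valued for
# non-star-convex outlines). The discrete Fourier transform
#   z_u = (1/K) * sum_k r_k exp(-2*pi*i*u*k/K)
# yields the raw descriptors; position invariance comes from nullifying z_0,
# size invariance from dividing by |z_1|, rotation invariance from keeping
# magnitudes only. The nine magnitudes |z_1|..|z_9| after normalization are
# the per-crypt shape features; their per-image average is the shape block
# of the 11-feature vector.

#' Radial signature of a closed boundary
#'
#' Samples the polar parametrization r(theta) of the boundary about a given
#' interior point at K equally spaced angles. Every angular bin is filled by
#' exact ray-polygon intersection; when a ray crosses the polygon more than
#' once the maximum crossing distance is taken.
#'
#' @param boundary a closed \linkS4class{Boundary}.
#' @param centroid length-2 interior point (x, y); defaults to the area
#'   centroid of the boundary.
#' @param K number of samples (even, >= 16).
#' @return Numeric vector of K radii, with the sample angles attached as
#'   attribute \code{"theta"}.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 65)[-65]
#' circ <- Boundary(cbind(10 * cos(th), 10 * sin(th)))
#' range(radialSignature(circ, c(0, 0), K = 32))
#' @export
radialSignature <- function(boundary, centroid = NULL, K = 64L) {
  stopifnot(is(boundary, "Boundary"), boundary@closed)
  K <- as.integer(K)
  if (K < 16L || K %% 2L != 0L) stop("K must be even and >= 16")
  V <- vertices(boundary)
  if (is.null(centroid)) centroid <- polygonCentroid(V)
  if (!pointInPolygon(centroid[1L], centroid[2L], V))
    stop("centroid lies outside the boundary (segmentation failure?)")
  theta <- 2 * pi * (0:(K - 1L)) / K
  r <- rayPolygonRadii(V, centroid, theta)
  if (anyNA(r) || any(r <= 0))
    stop("degenerate radial signature: ray without a boundary crossing")
  attr(r, "theta") <- theta
  r
}

#' Discrete Fourier transform of a radial signature
#'
#' Computes the K complex descriptors
#' \deqn{z_u = \frac{1}{K}\sum_{k=0}^{K-1} r_k e^{-2\pi i u k / K}}
#' (note the 1/K factor). The inverse transform recovers the samples to
#' numerical precision, and conjugate symmetry holds for real input.
#'
#' @param signature numeric vector of K radii (see
#'   \code{\link{radialSignature}}).
#' @return Complex vector of K raw descriptors.
#' @export
fourierDescriptors <- function(signature) {
  stopifnot(is.numeric(signature), length(signature) >= 2L)
  stats::fft(as.numeric(signature)) / length(signature)
}

#' Normalize raw Fourier descriptors to the 9 shape features
#'
#' Position invariance: the 0th-order coefficient is nullified (dropped).
#' Size invariance: the remaining coefficients are divided by |z_1|.
#' Rotation invariance: only magnitudes are kept. The output is
#' \eqn{|z_m| / |z_1|} for m = 1..9, so the first entry is exactly 1 for any
#' non-degenerate input. When |z_1| vanishes (below 1e-12 * |z_0|, or an
#' absolute 1e-12 when z_0 = 0) the shape is maximally regular under this
#' parametrization (e.g. a perfect circle) and the all-zero vector is
#' returned with the degenerate flag set.
#'
#' @param raw complex descriptor vector from
#'   \code{\link{fourierDescriptors}} (length >= 10).
#' @return Numeric vector \code{fd1..fd9} with attribute
#'   \code{"degenerate"}.
#' @export
normalizeDescriptors <- function(raw) {
  stopifnot(length(raw) >= 10L)
  eps <- if (Mod(raw[1L]) > 0) 1e-12 * Mod(raw[1L]) else 1e-12
  m1 <- Mod(raw[2L])
  if (m1 < eps) {
    out <- stats::setNames(numeric(9L), paste0("fd", 1:9))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- stats::setNames(Mod(raw[2:10]) / m1, paste0("fd", 1:9))
  attr(out, "degenerate") <- FALSE
  out
}

# Full per-crypt descriptor pipeline about the crypt's own mask centroid.
cryptDescriptors <- function(boundary, K = 64L) {
  ctr <- centroidFromBoundary(boundary)
  normalizeDescriptors(fourierDescriptors(
    radialSignature(boundary, c(ctr["x"], ctr["y"]), K = K)))
}

#' Average shape features of an image
#'
#' Component-wise arithmetic mean of the normalized descriptor vectors over
#' all non-degenerate crypts in a \linkS4class{ContourSet}. Degenerate crypts
#' (vanishing first-order coefficient) are excluded from the mean; when no
#' crypt is non-degenerate the all-zero vector is returned with attribute
#' \code{"allDegenerate"} set.
#'
#' @param contours a \linkS4class{ContourSet}.
#' @param K angular samples per crypt.
#' @return Named numeric vector \code{fd1..fd9} with attributes
#'   \code{"nCrypts"}, \code{"nDegenerate"} and \code{"allDegenerate"}.
#' @export
imageShapeFeatures <- function(contours, K = 64L) {
  stopifnot(is(contours, "ContourSet"))
  vecs <- lapply(crypts(contours), cryptDescriptors, K = K)
  deg <- vapply(vecs, function(v) isTRUE(attr(v, "degenerate")), logical(1))
  good <- vecs[!deg]
  out <- if (length(good)) colMeans(do.call(rbind, good))
         else stats::setNames(numeric(9L), paste0("fd", 1:9))
  attr(out, "nCrypts") <- length(vecs)
  attr(out, "nDegenerate") <- sum(deg)
  attr(out, "allDegenerate") <- length(good) == 0L
  out
}
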