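# Crypt-base to muscularis distance via first-order regression.
#
# A line y = a x + b is fitted (ordinary least squares) to the muscularis
# polyline vertices and to the base points of the first row of crypts;
# perpendicular norms from every muscularis vertex to the crypt line give the
# distance feature.

#' Ordinary least-squares line fit
#'
#' Closed-form minimizer of the mean squared error
#' \eqn{\mathrm{MSE} = \frac{1}{n}\sum_i (y_i - a x_i - b)^2}.
#'
#' @param points two-column matrix of (x, y) points; at least 2 points with
#'   at least 2 distinct x values.
#' @return List with slope \code{a}, intercept \code{b} and mean squared
#'   residual \code{mse}.
#' @examples
#' fitLine(cbind(0:4, 2 * (0:4) + 1))
#' @export
fitLine <- function(points) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2L, nrow(points) >= 2L)
  x <- points[, 1L]; y <- points[, 2L]
  sxx <- sum((x - mean(x))^2)
  if (sxx <= .Machine$double.eps * max(1, sum(x^2)))
    stop("degenerate orientation: all x values equal (vertical line)")
  a <- sum((x - mean(x)) * (y - mean(y))) / sxx
  b <- mean(y) - a * mean(x)
  list(a = a, b = b, mse = mean((y - a * x - b)^2))
}

# Perpendicular distance from points (px, py) to the line y = a x + b.
pointLineDistance <- function(px, py, fit) {
  abs(fit$a * px - py + fit$b) / sqrt(fit$a^2 + 1)
}

#' Base points of the first row of crypts
#'
#' The "first line of crypts" comprises the crypts whose centroid's
#' perpendicular distance to the muscularis line is within 1.5 times the
#' minimum such distance over all crypts; when fewer than two qualify, the
#' two nearest crypts are used. Each selected crypt contributes its boundary
#' vertex of minimal perpendicular distance to the muscularis line (its
#' base).
#'
#' @param crypts list of closed \linkS4class{Boundary} objects (>= 2).
#' @param muscularisFit line fit from \code{\link{fitLine}} on the
#'   muscularis vertices.
#' @param rowFactor selection threshold as a multiple of the minimum
#'   centroid distance.
#' @return Two-column matrix of base points, one row per selected crypt.
#' @export
cryptBasePoints <- function(crypts, muscularisFit, rowFactor = 1.5) {
  stopifnot(length(crypts) >= 2L)
  ctr <- t(vapply(crypts, function(b) polygonCentroid(vertices(b)), numeric(2)))
  dc <- pointLineDistance(ctr[, 1L], ctr[, 2L], muscularisFit)
  sel <- which(dc <= rowFactor * min(dc))
  if (length(sel) < 2L) sel <- order(dc)[1:2]
  t(vapply(crypts[sel], function(b) {
    V <- vertices(b)
    dv <- pointLineDistance(V[, 1L], V[, 2L], muscularisFit)
    V[which.min(dv), ]
  }, numeric(2)))
}

#' Normalized crypt-base to muscularis distance feature
#'
#' Fits a line to the muscularis vertices and a line to the crypt base
#' points, computes the perpendicular norm from every muscularis vertex to
#' the crypt line, and reports the mean norm divided by the image diagonal
#' (\code{mode = "scaled"}, the default: the gap magnitude itself,
#' scale-normalized). \code{mode = "ratio"} reports mean norm / max norm
#' instead, which is ~1 for near-parallel lines. When the muscularis is
#' absent or fewer than two crypts were found, the crypt-loss sentinel 1.0
#' is returned with attribute \code{"sentinel"} set.
#'
#' @param muscularis open \linkS4class{Boundary} (or \code{NULL}).
#' @param crypts list of closed \linkS4class{Boundary} objects.
#' @param imageDiag image diagonal in pixels (normalization scale).
#' @param mode \code{"scaled"} or \code{"ratio"}.
#' @return Normalized distance in [0, 1] with attributes \code{"sentinel"},
#'   \code{"meanNorm"}, \code{"maxNorm"} and \code{"ratio"}.
#' @export
muscularisDistanceFeature <- function(muscularis, crypts, imageDiag,
                                      mode = c("scaled", "ratio")) {
  mode <- match.arg(mode)
  if (is.null(muscularis) || length(crypts) < 2L) {
    out <- 1.0
    attr(out, "sentinel") <- TRUE
    return(out)
  }
  M <- vertices(muscularis)
  fm <- fitLine(M)
  base <- cryptBasePoints(crypts, fm)
  fc <- fitLine(base)
  norms <- pointLineDistance(M[, 1L], M[, 2L], fc)
  mn <- mean(norms); mx <- max(norms)
  out <- if (mode == "scaled") min(1, mn / imageDiag)
         else if (mx > 0) mn / mx else 1.0
  attr(out, "sentinel") <- FALSE
  attr(out, "meanNorm") <- mn
  attr(out, "maxNorm") <- mx
  attr(out, "ratio") <- if (mx > 0) mn / mx else 1.0
  out
}
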