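# Crypt density via image moments and the Euclidean minimum spanning tree.
#
# Crypt centroids come from the zeroth and first moments of the filled
# boundary mask, M_pq = sum_x sum_y x^p y^q f(x,y) with f the binary mask:
# xbar = M10/M00, ybar = M01/M00. The complete Euclidean graph over the
# centroids is reduced to its minimum spanning tree (Kruskal), and the
# density feature is the mean tree edge length normalized by the maximum
# tree edge length.

#' Mask-moment centroid of a closed boundary
#'
#' Fills the polygon (scanline over integer pixel centers) and computes the
#' discrete moments M00, M10, M01 of the binary mask; the centroid is
#' (M10/M00, M01/M00).
#'
#' @param boundary a closed, simple \linkS4class{Boundary}.
#' @return Named numeric vector \code{x}, \code{y}, \code{M00}.
#' @examples
#' sq <- Boundary(cbind(c(-0.5, 9.5, 9.5, -0.5), c(-0.5, -0.5, 4.5, 4.5)))
#' centroidFromBoundary(sq)
#' @export
centroidFromBoundary <- function(boundary) {
  stopifnot(is(boundary, "Boundary"), boundary@closed)
  px <- polygonPixels(vertices(boundary))
  if (nrow(px) == 0L) stop("zero-area boundary")
  m00 <- nrow(px)
  c(x = sum(px[, 1L]) / m00, y = sum(px[, 2L]) / m00, M00 = m00)
}

#' Euclidean minimum spanning tree (Kruskal)
#'
#' Kruskal's greedy algorithm over the complete Euclidean graph: edges are
#' sorted by (weight, i, j) with i < j — a stable order that makes the result
#' deterministic under ties — and accepted whenever they join two different
#' trees of the growing forest (union-find).
#'
#' @param points two-column matrix of point coordinates (n >= 1). Duplicate
#'   points are allowed and give zero-weight edges.
#' @return List with \code{edges} (data.frame \code{i}, \code{j},
#'   \code{weight}; n-1 rows, empty for n = 1) and \code{totalWeight}.
#' @examples
#' kruskalMST(cbind(c(0, 1, 2), c(0, 0, 0)))$totalWeight
#' @export
kruskalMST <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  stopifnot(n >= 1L, ncol(points) == 2L)
  if (n == 1L)
    return(list(edges = data.frame(i = integer(0), j = integer(0),
                                   weight = numeric(0)),
                totalWeight = 0))
  pr <- t(utils::combn(n, 2L))
  wts <- sqrt((points[pr[, 1L], 1L] - points[pr[, 2L], 1L])^2 +
                (points[pr[, 1L], 2L] - points[pr[, 2L], 2L])^2)
  ord <- order(wts, pr[, 1L], pr[, 2L])
  parent <- seq_len(n)
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  ei <- integer(n - 1L); ej <- integer(n - 1L); ew <- numeric(n - 1L)
  m <- 0L
  for (e in ord) {
    ra <- find(pr[e, 1L]); rb <- find(pr[e, 2L])
    if (ra != rb) {
      parent[ra] <- rb
      m <- m + 1L
      ei[m] <- pr[e, 1L]; ej[m] <- pr[e, 2L]; ew[m] <- wts[e]
      if (m == n - 1L) break
    }
  }
  list(edges = data.frame(i = ei, j = ej, weight = ew),
       totalWeight = sum(ew))
}

#' Normalized inter-crypt spacing feature
#'
#' Mean MST edge weight divided by the maximum MST edge weight (the
#' "maximum distance encountered" is read as the maximum distance in the
#' tree; set \code{denominator = "pairwise"} for the maximum pairwise
#' distance instead). The feature lies in (0, 1] and equals 1 exactly when
#' all tree edges are equal. With at most one centroid the image is
#' maximally sparse: the sentinel 1.0 is returned with attribute
#' \code{"sparse"} set.
#'
#' @param centroids two-column matrix of crypt centroids (rows), or a list of
#'   vectors as returned by \code{\link{centroidFromBoundary}}.
#' @param denominator \code{"mst"} (default) or \code{"pairwise"}.
#' @return Normalized spacing in (0, 1] with attributes \code{"sparse"},
#'   \code{"meanEdge"} and \code{"maxEdge"}.
#' @export
cryptSpacingFeature <- function(centroids, denominator = c("mst", "pairwise")) {
  denominator <- match.arg(denominator)
  if (is.list(centroids))
    centroids <- t(vapply(centroids, function(ct) ct[c("x", "y")], numeric(2)))
  centroids <- as.matrix(centroids)
  if (nrow(centroids) <= 1L) {
    out <- 1.0
    attr(out, "sparse") <- TRUE
    attr(out, "meanEdge") <- NA_real_
    attr(out, "maxEdge") <- NA_real_
    return(out)
  }
  mst <- kruskalMST(centroids[, 1:2, drop = FALSE])
  mn <- mean(mst$edges$weight)
  mx <- if (denominator == "mst") max(mst$edges$weight)
        else max(stats::dist(centroids[, 1:2, drop = FALSE]))
  out <- if (mx > 0) mn / mx else 1.0
  attr(out, "sparse") <- FALSE
  attr(out, "meanEdge") <- mn
  attr(out, "maxEdge") <- mx
  out
}
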