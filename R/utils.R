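# Internal geometry and RNG helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
withSeed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic child seed, kept inside 32-bit integer range.
childSeed <- function(seed, i) {
  as.integer((as.numeric(seed) * 10007 + as.numeric(i) * 97) %% 2147483647)
}

# Signed area of a closed polygon (positive = counter-clockwise in a y-up frame).
polygonArea <- function(V) {
  x <- V[, 1L]; y <- V[, 2L]
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  sum(x * y2 - x2 * y) / 2
}

polygonPerimeter <- function(V, closed = TRUE) {
  if (closed) W <- rbind(V, V[1L, , drop = FALSE]) else W <- V
  sum(sqrt(rowSums(diff(W)^2)))
}

# Area (shoelace) centroid of a closed polygon.
polygonCentroid <- function(V) {
  x <- V[, 1L]; y <- V[, 2L]
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  cr <- x * y2 - x2 * y
  A <- sum(cr) / 2
  if (abs(A) < .Machine$double.eps * 100)
    return(colMeans(V))
  c(sum((x + x2) * cr) / (6 * A), sum((y + y2) * cr) / (6 * A))
}

# Even-odd point-in-polygon test (vectorized over query points px, py).
pointInPolygon <- function(px, py, V) {
  x <- V[, 1L]; y <- V[, 2L]
  n <- length(x)
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  inside <- logical(length(px))
  for (e in seq_len(n)) {
    crosses <- (y[e] <= py & py < y2[e]) | (y2[e] <= py & py < y[e])
    if (any(crosses)) {
      t <- (py[crosses] - y[e]) / (y2[e] - y[e])
      xc <- x[e] + t * (x2[e] - x[e])
      inside[crosses] <- xor(inside[crosses], px[crosses] < xc)
    }
  }
  inside
}

# Integer pixel centers inside a closed polygon, by scanline fill.
# Returns a 2-column matrix of 0-based (x, y) coordinates.
polygonPixels <- function(V) {
  ylo <- ceiling(min(V[, 2L])); yhi <- floor(max(V[, 2L]))
  if (yhi < ylo) return(matrix(numeric(0), ncol = 2L))
  x <- V[, 1L]; y <- V[, 2L]
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  out <- vector("list", yhi - ylo + 1L)
  for (yy in ylo:yhi) {
    sel <- (y <= yy & yy < y2) | (y2 <= yy & yy < y)
    if (!any(sel)) next
    t <- (yy - y[sel]) / (y2[sel] - y[sel])
    xc <- sort(x[sel] + t * (x2[sel] - x[sel]))
    np <- length(xc) %/% 2L
    if (np == 0L) next
    spans <- lapply(seq_len(np), function(k) {
      a <- ceiling(xc[2L * k - 1L]); b <- floor(xc[2L * k])
      if (b < a) NULL else cbind(a:b, yy)
    })
    out[[yy - ylo + 1L]] <- do.call(rbind, spans)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) matrix(numeric(0), ncol = 2L) else res
}

# Proper-crossing test between segments (p1,p2) and (p3,p4); shared endpoints
# of consecutive polygon edges are not counted.
segmentsIntersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
     ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0)))
}

# Simplicity check for a closed polygon: no two non-adjacent edges cross.
isSimplePolygon <- function(V) {
  n <- nrow(V)
  W <- rbind(V, V[1L, , drop = FALSE])
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    js <- (i + 2L):jmax
    for (j in js) {
      if (segmentsIntersect(W[i, ], W[i + 1L, ], W[j, ], W[j + 1L, ]))
        return(FALSE)
    }
  }
  TRUE
}

# Exact radial distances from `ctr` to a closed polygon along rays at angles
# `theta`; the maximum crossing is taken when a ray crosses more than once.
rayPolygonRadii <- function(V, ctr, theta) {
  x <- V[, 1L] - ctr[1L]; y <- V[, 2L] - ctr[2L]
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  ex <- x2 - x; ey <- y2 - y
  vapply(theta, function(th) {
    dx <- cos(th); dy <- sin(th)
    den <- dy * ex - dx * ey
    t <- (dx * y - dy * x) / den
    s <- if (abs(dx) > abs(dy)) (x + t * ex) / dx else (y + t * ey) / dy
    ok <- is.finite(t) & t >= -1e-9 & t <= 1 + 1e-9 & s > 0
    if (!any(ok)) return(NA_real_)
    max(s[ok])
  }, numeric(1))
}

# Resample an ordered polyline (closed if `closed`) to n points equally spaced
# in arc length.
resamplePolyline <- function(V, n, closed = TRUE) {
  W <- if (closed) rbind(V, V[1L, , drop = FALSE]) else V
  seg <- sqrt(rowSums(diff(W)^2))
  keep <- c(TRUE, seg > 0)
  W <- W[keep, , drop = FALSE]
  seg <- seg[seg > 0]
  cum <- c(0, cumsum(seg))
  L <- cum[length(cum)]
  s <- if (closed) L * (0:(n - 1L)) / n else L * (0:(n - 1L)) / (n - 1L)
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx <- pmin(idx, length(seg))
  f <- (s - cum[idx]) / seg[idx]
  W[idx, , drop = FALSE] + f * (W[idx + 1L, , drop = FALSE] - W[idx, , drop = FALSE])
}

# Greedy nearest-pair matching between two point sets (rows). Returns a
# data.frame with indices into a and b and the pair distance; each point used
# at most once. Optimal when point sets are well separated relative to the
# matching tolerance in use.
matchPoints <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  if (na == 0L || nb == 0L)
    return(data.frame(i = integer(0), j = integer(0), dist = numeric(0)))
  D <- outer(seq_len(na), seq_len(nb), function(i, j)
    sqrt((a[i, 1L] - b[j, 1L])^2 + (a[i, 2L] - b[j, 2L])^2))
  usedA <- logical(na); usedB <- logical(nb)
  res <- list()
  for (k in seq_len(min(na, nb))) {
    D[usedA, ] <- Inf; D[, usedB] <- Inf
    m <- arrayInd(which.min(D), dim(D))
    if (!is.finite(D[m])) break
    res[[k]] <- data.frame(i = m[1L], j = m[2L], dist = D[m])
    usedA[m[1L]] <- TRUE; usedB[m[2L]] <- TRUE
  }
  do.call(rbind, res)
}
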