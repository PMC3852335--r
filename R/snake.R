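# Greedy active contour ("snake") on a discrete pixel grid.
#
# The total energy of a closed contour v_1..v_n is
#   E = sum_i alpha*E_cont_i + beta*E_curv_i + gamma*E_img_i + kappa*E_con_i
# with
#   E_cont_i = (|v_i - v_{i-1}| / d0)^2            (tension / continuity)
#   E_curv_i = (|v_{i-1} - 2 v_i + v_{i+1}| / d0)^2 (curvature)
#   E_img_i  = - |grad G_sigma * I|(v_i) / max     (edge attraction)
#   E_con_i  = (max(0, |v_i - c0| - 2 r0) / d0)^2  (containment beyond 2x
#                                                   the initial mean radius)
# d0, c0 and r0 are frozen from the initial contour, so the energy is a fixed
# function of the vertex configuration. Each vertex in turn greedily moves to
# the best position in a 7x7 window; a move is accepted only if it strictly
# lowers the affected energy terms, so the total energy is non-increasing
# across accepted iterations and the procedure is deterministic.

# Normalized gradient-magnitude energy of the smoothed image: -|grad|/max.
snakeEnergyImage <- function(clean, smoothSigma = 1.5) {
  m <- pixels(clean) / 255
  sm <- EBImage::gblur(m, sigma = smoothSigma)
  h <- nrow(sm); w <- ncol(sm)
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  gx[, 2:(w - 1L)] <- (sm[, 3:w] - sm[, 1:(w - 2L)]) / 2
  gy[2:(h - 1L), ] <- (sm[3:h, ] - sm[1:(h - 2L), ]) / 2
  G <- sqrt(gx^2 + gy^2)
  mx <- max(G)
  if (mx > 0) G <- G / mx
  -G
}

#' Evolve a snake to a nearby energy minimum
#'
#' Greedy discrete evolution of a closed contour under the energy model
#' described above. Terminates when no vertex moves by \code{moveTol} or more
#' during a sweep, or after \code{maxIters} sweeps. The per-sweep energy,
#' perimeter and maximum vertex displacement are attached as attribute
#' \code{"trace"}; a contour that collapses below 3 square pixels of area is
#' returned unevolved with attribute \code{"failed"} set.
#'
#' @param initial closed \linkS4class{Boundary} to start from.
#' @param clean cleaned \linkS4class{BiopsyImage}.
#' @param config a \linkS4class{SnakeConfig}.
#' @param energyImage optional precomputed result of the internal image-energy
#'   transform (reused across snakes on the same image).
#' @return The evolved closed \linkS4class{Boundary} with attributes
#'   \code{"trace"} (matrix with columns energy, perimeter, maxMove) and
#'   \code{"converged"}.
#' @export
evolveSnake <- function(initial, clean, config = snakeConfig(),
                        energyImage = NULL) {
  stopifnot(is(initial, "Boundary"), initial@closed, is(clean, "BiopsyImage"))
  E <- if (is.null(energyImage)) snakeEnergyImage(clean) else energyImage
  h <- nrow(E); w <- ncol(E)
  V <- round(vertices(initial))
  V[, 1L] <- pmin(pmax(V[, 1L], 0), w - 1L)
  V[, 2L] <- pmin(pmax(V[, 2L], 0), h - 1L)
  # drop consecutive duplicates introduced by rounding
  keep <- c(TRUE, rowSums(abs(diff(V))) > 0)
  if (sum(keep) < 4L) {
    out <- initial; attr(out, "failed") <- TRUE; return(out)
  }
  V <- V[keep, , drop = FALSE]
  n <- nrow(V)
  al <- config@alpha; be <- config@beta; ga <- config@gamma; ka <- config@kappa

  c0 <- polygonCentroid(V)
  r0 <- mean(sqrt((V[, 1L] - c0[1L])^2 + (V[, 2L] - c0[2L])^2))
  d0 <- polygonPerimeter(V) / n
  if (d0 <= 0) d0 <- 1

  off <- as.matrix(expand.grid(dx = -3:3, dy = -3:3))
  wrap <- function(i) ((i - 1L) %% n) + 1L

  conE <- function(px, py) {
    r <- sqrt((px - c0[1L])^2 + (py - c0[2L])^2)
    (pmax(0, r - 2 * r0) / d0)^2
  }
  imgE <- function(px, py) E[cbind(py + 1L, px + 1L)]
  totalEnergy <- function(V) {
    prv <- V[wrap(seq_len(n) - 1L), , drop = FALSE]
    nxt <- V[wrap(seq_len(n) + 1L), , drop = FALSE]
    cont <- rowSums((V - prv)^2) / d0^2
    curv <- rowSums((prv - 2 * V + nxt)^2) / d0^2
    sum(al * cont + be * curv + ga * imgE(V[, 1L], V[, 2L]) +
          ka * conE(V[, 1L], V[, 2L]))
  }

  trace <- matrix(NA_real_, nrow = 0L, ncol = 3L,
                  dimnames = list(NULL, c("energy", "perimeter", "maxMove")))
  converged <- FALSE
  for (iter in seq_len(config@maxIters)) {
    maxMove <- 0
    for (i in seq_len(n)) {
      im2 <- wrap(i - 2L); im1 <- wrap(i - 1L)
      ip1 <- wrap(i + 1L); ip2 <- wrap(i + 2L)
      px <- V[i, 1L] + off[, 1L]; py <- V[i, 2L] + off[, 2L]
      okb <- px >= 0 & px <= w - 1L & py >= 0 & py <= h - 1L
      cand <- rep(Inf, nrow(off))
      cont <- ((px - V[im1, 1L])^2 + (py - V[im1, 2L])^2 +
                 (V[ip1, 1L] - px)^2 + (V[ip1, 2L] - py)^2) / d0^2
      curv <- ((V[im2, 1L] - 2 * V[im1, 1L] + px)^2 +
                 (V[im2, 2L] - 2 * V[im1, 2L] + py)^2 +
                 (V[im1, 1L] - 2 * px + V[ip1, 1L])^2 +
                 (V[im1, 2L] - 2 * py + V[ip1, 2L])^2 +
                 (px - 2 * V[ip1, 1L] + V[ip2, 1L])^2 +
                 (py - 2 * V[ip1, 2L] + V[ip2, 2L])^2) / d0^2
      cand[okb] <- (al * cont + be * curv)[okb] +
        ga * imgE(px[okb], py[okb]) + ka * conE(px[okb], py[okb])
      cur <- cand[off[, 1L] == 0 & off[, 2L] == 0]
      best <- which.min(cand)
      if (cand[best] < cur - 1e-12) {
        move <- sqrt(sum((c(px[best], py[best]) - V[i, ])^2))
        maxMove <- max(maxMove, move)
        V[i, ] <- c(px[best], py[best])
      }
    }
    trace <- rbind(trace, c(totalEnergy(V), polygonPerimeter(V), maxMove))
    if (maxMove < config@moveTol) { converged <- TRUE; break }
  }

  if (abs(polygonArea(V)) < 3) {
    out <- initial
    attr(out, "failed") <- TRUE
    attr(out, "trace") <- trace
    return(out)
  }
  keep <- c(TRUE, rowSums(abs(diff(V))) > 0)
  if (nrow(V) >= 2L && all(V[nrow(V), ] == V[1L, ])) keep[nrow(V)] <- FALSE
  V <- V[keep, , drop = FALSE]
  if (nrow(V) < 3L) {
    out <- initial
    attr(out, "failed") <- TRUE
    attr(out, "trace") <- trace
    return(out)
  }
  out <- Boundary(V, closed = TRUE)
  attr(out, "trace") <- trace
  attr(out, "converged") <- converged
  out
}
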