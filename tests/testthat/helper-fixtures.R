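# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

# A light-background image with one dark disk.
diskImage <- function(size = c(120L, 120L), center = c(60, 60), radius = 25,
                      bg = 200, fg = 60) {
  m <- matrix(bg, nrow = size[1L], ncol = size[2L])
  xs <- matrix(rep(0:(size[2L] - 1L), each = size[1L]), nrow = size[1L])
  ys <- matrix(rep(0:(size[1L] - 1L), times = size[2L]), nrow = size[1L])
  m[(xs - center[1L])^2 + (ys - center[2L])^2 <= radius^2] <- fg
  BiopsyImage(m)
}

# Regular polygon approximating a circle; M a multiple of 4 keeps the
# axis-aligned extreme points exact.
circleBoundary <- function(radius, center = c(0, 0), M = 256L) {
  th <- 2 * pi * (0:(M - 1L)) / M
  Boundary(cbind(center[1L] + radius * cos(th), center[2L] + radius * sin(th)))
}

# One small rendered synthetic field per grade, reused across files.
smallSim <- function(grade = "Normal", seed = 5L)
  fixture(paste0("sim-", grade, "-", seed),
          generateBiopsyImage(gradeParams(grade), width = 400L, height = 300L,
                              seed = seed))

# A small rendered cohort with extracted features (12 images, 400x300).
miniCohortFeatures <- function() {
  fixture("miniCohortFeatures", {
    coh <- generateCohort(3L, seed = 99L, width = 400L, height = 300L)
    list(cohort = coh, features = cohortFeatures(coh))
  })
}

# Literal O(K^2) DFT of Eq-style convention (1/K sum r e^{-2pi i uk/K}).
dftOracle <- function(r) {
  K <- length(r)
  vapply(0:(K - 1L), function(u)
    sum(r * exp(-2i * pi * u * (0:(K - 1L)) / K)) / K, complex(1))
}

# Exhaustive minimum spanning weight by Pruefer enumeration (n <= 7).
exhaustiveMSTWeight <- function(points) {
  n <- nrow(points)
  D <- as.matrix(dist(points))
  if (n == 1L) return(0)
  if (n == 2L) return(D[1L, 2L])
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
  best <- Inf
  for (s in seq_len(nrow(seqs))) {
    pruefer <- seqs[s, ]
    degree <- rep(1L, n)
    for (v in pruefer) degree[v] <- degree[v] + 1L
    w <- 0
    avail <- degree
    pr <- pruefer
    for (k in seq_along(pr)) {
      leaf <- which(avail == 1L)[1L]
      w <- w + D[leaf, pr[k]]
      avail[leaf] <- 0L
      avail[pr[k]] <- avail[pr[k]] - 1L
    }
    ends <- which(avail == 1L)
    w <- w + D[ends[1L], ends[2L]]
    if (w < best) best <- w
  }
  best
}

# Seeded uniform draws that restore the caller's RNG state.
withr_seed_runif <- function(seed, n, lo = 5, hi = 15) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  runif(n, lo, hi)
}

withSeedMatrix <- function(seed, n, d) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  matrix(runif(n * d), nrow = n)
}
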