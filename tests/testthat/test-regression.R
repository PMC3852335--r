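test_that("least-squares line fit is exact, optimal and matches lm", {
  f <- fitLine(cbind(0:4, 2 * (0:4) + 1))
  expect_equal(f$a, 2); expect_equal(f$b, 1); expect_equal(f$mse, 0)

  f <- fitLine(cbind(c(0, 1, 2), c(0, 1, 0)))
  expect_equal(f$a, 0)
  expect_equal(f$b, 1 / 3)
  expect_equal(f$mse, 2 / 9)

  pts <- cbind(withr_seed_runif(3L, 12L), withr_seed_runif(13L, 12L))
  f <- fitLine(pts)
  co <- stats::coef(stats::lm(pts[, 2L] ~ pts[, 1L]))
  expect_equal(f$a, unname(co[2L]), tolerance = 1e-10)
  expect_equal(f$b, unname(co[1L]), tolerance = 1e-10)
  mseAt <- function(a, b) mean((pts[, 2L] - a * pts[, 1L] - b)^2)
  for (d in c(-1e-3, 1e-3)) {
    expect_lte(f$mse, mseAt(f$a + d, f$b))
    expect_lte(f$mse, mseAt(f$a, f$b + d))
  }

  expect_error(fitLine(cbind(c(2, 2, 2), c(0, 1, 2))), "degenerate")
})

test_that("crypt base points sit at the tangency and come from the first row", {
  musc <- fitLine(cbind(c(0, 200), c(100, 100)))
  circles <- list(circleBoundary(30, c(50, 70), M = 256L),
                  circleBoundary(30, c(130, 70), M = 256L))
  base <- cryptBasePoints(circles, musc)
  expect_equal(nrow(base), 2L)
  expect_lt(max(abs(base[, 2L] - 100)), 1)

  rows <- list(circleBoundary(20, c(50, 50), M = 128L),
               circleBoundary(20, c(150, 50), M = 128L),
               circleBoundary(20, c(50, 150), M = 128L),
               circleBoundary(20, c(150, 150), M = 128L))
  muscLow <- fitLine(cbind(c(0, 200), c(200, 200)))
  base <- cryptBasePoints(rows, muscLow)
  expect_equal(nrow(base), 2L)
  expect_true(all(base[, 2L] > 140))  # only the lower row is selected
})

test_that("distance feature matches parallel and tilted closed forms", {
  musc <- Boundary(cbind(seq(0, 200, by = 10), 150), closed = FALSE)
  crypts <- list(circleBoundary(25, c(50, 75), M = 256L),
                 circleBoundary(25, c(150, 75), M = 256L))
  f <- muscularisDistanceFeature(musc, crypts, imageDiag = 1000)
  expect_equal(attr(f, "ratio"), 1, tolerance = 1e-6)
  expect_equal(as.numeric(f), 0.05, tolerance = 1e-3)

  # crypt line y = 0.1 x + 100 via two triangle "crypts" with their base
  # vertices exactly on it; muscularis flat at y = 200
  tri <- function(bx, by)
    Boundary(cbind(c(bx, bx - 6, bx + 6), c(by, by - 14, by - 14)))
  xs <- seq(0, 100, by = 10)
  musc2 <- Boundary(cbind(xs, 200), closed = FALSE)
  f2 <- muscularisDistanceFeature(musc2, list(tri(0, 100), tri(100, 110)),
                                  imageDiag = 1000)
  norms <- (100 - 0.1 * xs) / sqrt(1 + 0.1^2)
  expect_equal(attr(f2, "meanNorm"), mean(norms), tolerance = 1e-9)
  expect_equal(attr(f2, "ratio"), mean(norms) / max(norms), tolerance = 1e-9)
  expect_equal(as.numeric(f2), mean(norms) / 1000, tolerance = 1e-9)

  # paper-literal reading behind the mode switch
  fr <- muscularisDistanceFeature(musc2, list(tri(0, 100), tri(100, 110)),
                                  imageDiag = 1000, mode = "ratio")
  expect_equal(as.numeric(fr), mean(norms) / max(norms), tolerance = 1e-9)
})

test_that("sentinels fire without muscularis or with too few crypts", {
  crypts <- list(circleBoundary(10, c(30, 30)), circleBoundary(10, c(80, 30)))
  f <- muscularisDistanceFeature(NULL, crypts, imageDiag = 500)
  expect_equal(as.numeric(f), 1.0)
  expect_true(attr(f, "sentinel"))

  musc <- Boundary(cbind(c(0, 100), c(90, 90)), closed = FALSE)
  f <- muscularisDistanceFeature(musc, crypts[1L], imageDiag = 500)
  expect_true(attr(f, "sentinel"))
})

test_that("feature is translation invariant and cancels uniform rescaling", {
  musc <- Boundary(cbind(seq(0, 300, by = 20), 250 + 0.05 * seq(0, 300, by = 20)),
                   closed = FALSE)
  crypts <- list(circleBoundary(22, c(60, 120), M = 128L),
                 circleBoundary(22, c(160, 130), M = 128L),
                 circleBoundary(22, c(260, 140), M = 128L))
  f0 <- as.numeric(muscularisDistanceFeature(musc, crypts, imageDiag = 1000))

  shift <- function(b, d) Boundary(sweep(vertices(b), 2L, d, `+`),
                                   closed = isClosed(b))
  f1 <- as.numeric(muscularisDistanceFeature(
    shift(musc, c(31, 0)), lapply(crypts, shift, d = c(31, 0)),
    imageDiag = 1000))
  expect_equal(f1, f0, tolerance = 1e-9)

  scale2 <- function(b) Boundary(vertices(b) * 2, closed = isClosed(b))
  f2 <- as.numeric(muscularisDistanceFeature(
    scale2(musc), lapply(crypts, scale2), imageDiag = 2000))
  expect_equal(f2, f0, tolerance = 1e-9)
})

test_that("ground-truth basal gap drives the distance feature and its recovery", {
  contourSetFromTruth <- function(truth) {
    ContourSet(crypts = cryptBoundaries(truth),
               muscularis = Boundary(muscularis(truth), closed = FALSE))
  }
  featForGrade <- function(grade, seeds) {
    vapply(seeds, function(s) {
      sim <- generateBiopsyImage(gradeParams(grade), seed = s, render = FALSE)
      as.numeric(muscularisDistanceFeature(
        Boundary(muscularis(sim$truth), closed = FALSE),
        cryptBoundaries(sim$truth), imageDiag = 1000))
    }, numeric(1))
  }
  lo <- featForGrade("Normal", 700 + 1:20)   # basal gap 15
  hi <- featForGrade("III", 700 + 1:20)      # basal gap 60
  expect_gt(mean(hi), mean(lo))

  # fitted gap close to the nominal ground-truth gap on one field
  sim <- generateBiopsyImage(gradeParams("II"), seed = 99L, render = FALSE)
  cs <- contourSetFromTruth(sim$truth)
  M <- vertices(muscularis(cs))
  fm <- fitLine(M)
  base <- cryptBasePoints(crypts(cs), fm)
  fc <- fitLine(base)
  mid <- mean(range(M[, 1L]))
  gapFit <- cryptArch:::pointLineDistance(mid, fc$a * mid + fc$b, fm)
  expect_lt(abs(gapFit - gradeParams("II")@basalGap), 5)
})
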