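# Training set whose scaler is the identity: corner patterns pin the
# per-feature min to 0 and max to 1.
cornerTraining <- function(p = rep(0.5, 11)) {
  x <- rbind(p, rep(0, 11), rep(1, 11), rep(0.9, 11))
  rownames(x) <- NULL
  list(features = x, labels = c("Normal", "I", "II", "III"))
}

test_that("training stores patterns verbatim with the stated architecture", {
  tr <- cornerTraining()
  m <- trainPNN(tr$features, tr$labels, sigma = 0.3)
  expect_identical(nrow(m@patterns), 4L)           # one hidden node per pattern
  expect_identical(nlevels(m@labels), 4L)          # one class node per grade
  expect_equal(unname(m@patterns), unname(tr$features))  # identity scaler

  counts <- c(29L, 26L, 17L, 7L)
  cl <- syntheticFeatureClusters(counts, seed = 3L)
  m2 <- suppressWarnings(trainPNN(cl$features, cl$labels, sigma = 0.1))
  expect_equal(m2@priors, counts / sum(counts))
  m3 <- suppressWarnings(trainPNN(cl$features, cl$labels, sigma = 0.1,
                                  priorsMode = "uniform"))
  expect_equal(m3@priors, rep(0.25, 4))

  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  writePNNModel(suppressWarnings(trainPNN(cl$features, cl$labels, 0.1)), f1)
  writePNNModel(suppressWarnings(trainPNN(cl$features, cl$labels, 0.1)), f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(trainPNN(tr$features[1:2, ], c("Normal", "Normal"), 0.1),
               "2 classes")
})

test_that("class densities follow the Gaussian kernel closed form", {
  tr <- cornerTraining()
  m <- trainPNN(tr$features, tr$labels, sigma = 0.1)
  expect_equal(classDensity(m, rep(0.5, 11), "Normal"), 1)

  d <- sqrt(2 * 0.1^2)
  q <- c(0.5 + d, rep(0.5, 10))
  expect_equal(classDensity(m, q, "Normal"), exp(-1), tolerance = 1e-12)

  # brute-force direct-summation oracle on a random model
  cl <- syntheticFeatureClusters(c(6L, 5L, 4L, 3L), seed = 8L, spread = 0.05)
  m2 <- suppressWarnings(trainPNN(cl$features, cl$labels, sigma = 0.2))
  qs <- syntheticFeatureClusters(c(2L, 2L, 2L, 2L), seed = 9L)$features
  for (i in seq_len(nrow(qs))) {
    vs <- cryptArch:::scaleFeatures(qs[i, , drop = FALSE],
                                    m2@scalerMin, m2@scalerMax)
    for (g in gradeLevels()) {
      idx <- which(m2@labels == g)
      acc <- 0
      for (j in idx)
        acc <- acc + exp(-sum((vs - m2@patterns[j, ])^2) / (2 * m2@sigma^2))
      expect_equal(classDensity(m2, qs[i, ], g), acc / length(idx),
                   tolerance = 1e-12)
    }
  }
})

test_that("the decision rule picks the max score and breaks ties downward", {
  tr <- cornerTraining(p = rep(0.1, 11))
  m <- trainPNN(tr$features, tr$labels, sigma = 0.15, priorsMode = "uniform")
  expect_identical(classifyPNN(m, rep(1, 11))$grade, "II")

  # query equidistant from the Normal and I patterns, far from others
  # (0, 0.25 and 0.5 are exact in binary, so the tie is exact)
  x <- rbind(rep(0, 11), rep(0.5, 11), rep(1, 11), rep(0.75, 11))
  lab <- c("Normal", "I", "II", "III")
  m2 <- trainPNN(x, lab, sigma = 0.1, priorsMode = "uniform")
  mid <- rep(0.25, 11)
  cls <- classifyPNN(m2, mid)
  expect_equal(cls$scores[["Normal"]], cls$scores[["I"]], tolerance = 1e-15)
  expect_identical(cls$grade, "Normal")
  expect_length(cls$scores, 4L)
})

test_that("vanishing sigma reduces the decision to nearest neighbor", {
  cl <- syntheticFeatureClusters(c(9L, 8L, 6L, 4L), seed = 12L, spread = 0.06)
  m <- suppressWarnings(trainPNN(cl$features, cl$labels, sigma = 1e-5))
  queries <- withSeedMatrix(13L, 100L, 11L)
  for (i in seq_len(nrow(queries))) {
    q <- queries[i, ]
    vs <- cryptArch:::scaleFeatures(matrix(q, nrow = 1L),
                                    m@scalerMin, m@scalerMax)
    d2 <- rowSums(sweep(m@patterns, 2L, vs)^2)
    nn <- as.character(m@labels[which.min(d2)])
    expect_identical(suppressWarnings(classifyPNN(m, q)$grade), nn)
  }
})


test_that("decisions are invariant to a common loss rescaling", {
  cl <- syntheticFeatureClusters(c(7L, 6L, 5L, 4L), seed = 21L, spread = 0.05)
  m1 <- suppressWarnings(trainPNN(cl$features, cl$labels, sigma = 0.15))
  m2 <- suppressWarnings(trainPNN(cl$features, cl$labels, sigma = 0.15,
                                  losses = rep(7.3, 4)))
  queries <- withSeedMatrix(22L, 50L, 11L)
  g1 <- apply(queries, 1L, function(q) classifyPNN(m1, q)$grade)
  g2 <- apply(queries, 1L, function(q) classifyPNN(m2, q)$grade)
  expect_identical(g1, g2)
})

test_that("sigma selection maximizes leave-one-out accuracy deterministically", {
  cl <- syntheticFeatureClusters(c(8L, 7L, 5L, 4L), seed = 30L, spread = 0.02)
  sg <- suppressWarnings(
    selectSigma(cl$features, cl$labels, grid = c(0.01, 0.05, 0.2)))
  expect_equal(attr(sg, "looAccuracy"), 1.0)

  one <- suppressWarnings(selectSigma(cl$features, cl$labels, grid = 0.37))
  expect_equal(as.numeric(one), 0.37)

  sg2 <- suppressWarnings(
    selectSigma(cl$features, cl$labels, grid = c(0.2, 0.01, 0.05)))
  expect_equal(as.numeric(sg2), as.numeric(sg))
})

test_that("small sigma memorizes the training set", {
  cl <- syntheticFeatureClusters(c(8L, 7L, 5L, 3L), seed = 44L, spread = 0.03)
  m0 <- suppressWarnings(trainPNN(cl$features, cl$labels, sigma = 1))
  dmin <- min(stats::dist(m0@patterns))
  m <- suppressWarnings(trainPNN(cl$features, cl$labels, sigma = 0.4 * dmin))
  pred <- apply(cl$features, 1L, function(q)
    suppressWarnings(classifyPNN(m, q)$grade))
  expect_identical(unname(pred), cl$labels)
})

test_that("serialization round-trips bit-compatible decisions", {
  cl <- syntheticFeatureClusters(c(6L, 6L, 5L, 4L), seed = 50L, spread = 0.05)
  m <- suppressWarnings(trainPNN(cl$features, cl$labels, sigma = 0.12))
  path <- tempfile(fileext = ".json")
  writePNNModel(m, path)
  m2 <- readPNNModel(path)
  expect_equal(m2@patterns, m@patterns)
  expect_identical(as.character(m2@labels), as.character(m@labels))
  queries <- withSeedMatrix(51L, 100L, 11L)
  for (i in seq_len(nrow(queries))) {
    expect_identical(classifyPNN(m2, queries[i, ])$grade,
                     classifyPNN(m, queries[i, ])$grade)
  }
})
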