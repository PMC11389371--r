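test_that("naive modes reproduce a constant profile and the preceding sample", {
  m <- matrix(rep(c(0.6, 0.3, 0.1), 4), 4, byrow = TRUE,
              dimnames = list(NULL, c("A", "B", "C")))
  p <- LongitudinalProfile(m, times = c(0, 2, 5, 7), individualId = "c")
  for (mode in c("mean", "median", "last"))
    expect_equal(unname(interpolateNaive(p, 4, mode)), c(0.6, 0.3, 0.1))

  # two antipodal samples, mean at any interior time
  p2 <- LongitudinalProfile(rbind(c(1, 0), c(0, 1)) + 0,
                            times = c(0, 10), individualId = "x")
  expect_equal(unname(interpolateNaive(p2, 3, "mean")), c(0.5, 0.5))

  # 'last' picks the sample immediately preceding the target
  m3 <- rbind(c(0.7, 0.3), c(0.2, 0.8), c(0.5, 0.5))
  colnames(m3) <- c("A", "B")
  p3 <- LongitudinalProfile(m3, times = c(0, 2, 5), individualId = "x")
  expect_equal(unname(interpolateNaive(p3, 4, "last")), c(0.2, 0.8))
  expect_error(interpolateNaive(p3, -1, "last"), "precedes")
})

test_that("equal null is uniform with maximal Shannon diversity", {
  x <- interpolateEqual(31)
  expect_equal(x, rep(1 / 31, 31))
  expect_equal(shannonDiversity(x), log(31))
  expect_equal(interpolateEqual(1), 1)
})

test_that("weighted average is the convex combination of bracketing samples", {
  p <- LongitudinalProfile(rbind(c(1, 0), c(0, 1)) + 0,
                           times = c(0, 10), individualId = "x")
  expect_equal(unname(interpolateWeightedAverage(p, 2)), c(0.8, 0.2))
  # identical endpoints reproduce themselves anywhere inside
  pc <- LongitudinalProfile(rbind(c(0.4, 0.6), c(0.4, 0.6)),
                            times = c(0, 5), individualId = "x")
  expect_equal(unname(interpolateWeightedAverage(pc, 3.7)), c(0.4, 0.6))
  # boundary limit t -> t1 recovers x1
  expect_equal(unname(interpolateWeightedAverage(p, 1e-12)), c(1, 0),
               tolerance = 1e-10)
  expect_error(interpolateWeightedAverage(p, 11), "strictly before and after")
})

test_that("weighted average equals per-taxon linear interpolation", {
  for (case in 1:100) {
    p <- randomProfile(6, 4, seed = 1000 + case)
    tms <- sampleTimes(p)
    target <- runif(1, tms[2], tms[5])
    if (target %in% tms) next
    got <- interpolateWeightedAverage(p, target)
    oracle <- apply(abundanceMatrix(p), 2, function(y)
      approx(tms, y, xout = target)$y)
    expect_lt(max(abs(got - oracle)), 1e-12)
  }
})

test_that("KNN applies Epanechnikov weights with zero weight on the farthest", {
  # neighbour offsets -2,-1,+1,+2,+3 around the target:
  # raw weights 5/12, 2/3, 2/3, 5/12, 0
  set.seed(30)
  m <- matrix(rgamma(15, 1), 5, 3, dimnames = list(NULL, c("A", "B", "C")))
  p <- LongitudinalProfile(m, times = c(0, 1, 3, 4, 5), individualId = "x")
  target <- 2
  ab <- abundanceMatrix(p)
  w <- c(5 / 12, 2 / 3, 2 / 3, 5 / 12, 0)
  oracle <- normalizeComposition(drop(w %*% ab))
  expect_equal(unname(interpolateKNN(p, target, K = 5)), unname(oracle))

  # the farthest neighbour's composition is irrelevant
  m2 <- m
  m2[5, ] <- c(5, 1, 14)
  p2 <- LongitudinalProfile(m2, times = c(0, 1, 3, 4, 5), individualId = "x")
  expect_equal(interpolateKNN(p2, target, K = 5),
               interpolateKNN(p, target, K = 5))
})

test_that("KNN with K=2 collapses onto the nearer neighbour, K=1 is nearest", {
  m <- rbind(c(0.9, 0.1), c(0.3, 0.7), c(0.5, 0.5))
  colnames(m) <- c("A", "B")
  p <- LongitudinalProfile(m, times = c(0, 5, 6), individualId = "x")
  # target one day before the nearer of two right-hand neighbours: the
  # farther of the two selected samples gets exactly zero kernel weight
  expect_equal(unname(interpolateKNN(p, 4, K = 2)), c(0.3, 0.7))
  expect_equal(unname(interpolateKNN(p, 4.4, K = 1)), c(0.3, 0.7))
})

test_that("KNN resolves ties toward the earlier sample and degenerate spreads uniformly", {
  m <- rbind(c(0.8, 0.2), c(0.4, 0.6), c(0.1, 0.9))
  colnames(m) <- c("A", "B")
  p <- LongitudinalProfile(m, times = c(0, 2, 4), individualId = "x")
  # samples at day 0 and day 2 are equidistant from 1; K=1 takes the earlier
  expect_equal(unname(interpolateKNN(p, 1, K = 1)), c(0.8, 0.2))
  # K=2 selects both equidistant samples; all kernel weights vanish, so the
  # uniform fallback averages them
  expect_equal(unname(interpolateKNN(p, 1, K = 2)),
               normalizeComposition(c(0.6, 0.4)))
})

test_that("KNN with identical neighbours reproduces the shared composition", {
  m <- matrix(rep(c(0.25, 0.75), 5), 5, byrow = TRUE,
              dimnames = list(NULL, c("A", "B")))
  p <- LongitudinalProfile(m, times = c(0, 1, 3, 6, 7), individualId = "x")
  expect_equal(unname(interpolateKNN(p, 2, K = 5)), c(0.25, 0.75))
})

test_that("spline reproduces constants and exact cubics, clips negatives", {
  m <- matrix(rep(c(0.3, 0.7), 6), 6, byrow = TRUE,
              dimnames = list(NULL, c("A", "B")))
  p <- LongitudinalProfile(m, times = c(0, 1, 2, 4, 5, 7), individualId = "x")
  expect_equal(unname(interpolateSpline(p, 3)), c(0.3, 0.7))

  # taxon abundances that are exact cubics in t (rows sum to 1 by
  # construction, so renormalization is a no-op and the raw spline value
  # is observable)
  tms <- c(0, 1, 2.5, 4, 5.5, 7)
  f <- function(t) 0.3 + 0.02 * t - 0.004 * t^2 + 0.0004 * t^3
  m2 <- cbind(A = f(tms), B = 1 - f(tms))
  p2 <- LongitudinalProfile(m2, times = tms, individualId = "x")
  tt <- 3.3
  expect_lt(abs(interpolateSpline(p2, tt)[["A"]] - f(tt)), 1e-8)

  # overshoot: a taxon pinned at 0 inside a steep descent goes negative
  g <- c(0.5, 0.25, 0.02, 0, 0, 0.3)
  m3 <- cbind(A = g, B = 1 - g)
  p3 <- LongitudinalProfile(m3, times = 0:5, individualId = "x")
  got <- interpolateSpline(p3, 3.5)
  expect_identical(got[["A"]], 0)
  expect_equal(sum(got), 1)
})

test_that("spline degrades to quadratic/linear interpolation below 4 samples", {
  m <- cbind(A = c(0.2, 0.5, 0.4), B = c(0.8, 0.5, 0.6))
  p3 <- LongitudinalProfile(m, times = c(0, 1, 3), individualId = "x")
  co <- pracma::polyfit(c(0, 1, 3), m[, 1], 2)
  expect_equal(interpolateSpline(p3, 2)[["A"]], pracma::polyval(co, 2))
  p2 <- LongitudinalProfile(m[1:2, ], times = c(0, 1), individualId = "x")
  expect_equal(unname(interpolateSpline(p2, 0.5)), c(0.35, 0.65))
})

test_that("every registered interpolator outputs a simplex vector deterministically", {
  p <- randomProfile(12, 6, seed = 77)
  target <- mean(sampleTimes(p)[6:7])
  for (m in interpolationMethods()) {
    a <- interpolateAt(p, target, m, seed = 5)
    b <- interpolateAt(p, target, m, seed = 5)
    expect_equal(a, b, info = m)
    expect_true(all(a >= 0), info = m)
    expect_equal(sum(a), 1, tolerance = 1e-9, info = m)
  }
  expect_error(interpolateAt(p, target, "nope"))
})
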