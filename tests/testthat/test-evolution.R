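test_that("regularized Heaviside has the arctan form", {
  expect_equal(regHeaviside(0, 1), 0.5)
  expect_equal(regHeaviside(0, 0.37), 0.5)
  expect_equal(regHeaviside(1, 1), 0.75)        # arctan(1) = pi/4
  expect_equal(regHeaviside(2.5, 2.5), 0.75)
  z <- seq(-5, 5, by = 0.1)
  expect_true(all(diff(regHeaviside(z, 1)) > 0))       # strictly monotone
  expect_true(all(regHeaviside(z, 1) > 0 & regHeaviside(z, 1) < 1))
  expect_lt(abs(regHeaviside(100, 1) - 1), 0.01)
  expect_lt(abs(regHeaviside(-100, 1) - 0), 0.01)
  expect_error(regHeaviside(1, 0), "positive")
})

test_that("regularized Dirac is the Heaviside derivative", {
  for (eps in c(0.5, 1, 2)) {
    expect_equal(regDirac(0, eps), 1 / (pi * eps))
    z <- seq(0.1, 50, by = 0.7)
    expect_equal(regDirac(z, eps), regDirac(-z, eps))   # even
    expect_true(all(regDirac(z, eps) < regDirac(0, eps)))
    # unit mass
    expect_equal(
      integrate(regDirac, -1000 * eps, 1000 * eps, epsilon = eps)$value,
      1, tolerance = 1e-3)
    # numerical derivative of H matches delta
    h <- 1e-5
    zz <- c(-3, -0.7, 0, 1.2, 4)
    expect_equal((regHeaviside(zz + h, eps) - regHeaviside(zz - h, eps)) /
                   (2 * h),
                 regDirac(zz, eps), tolerance = 1e-6)
  }
  expect_error(regDirac(1, -1), "positive")
})

test_that("mean update matches the literal neighborhood double sum", {
  set.seed(5)
  for (n in c(5, 8)) {
    img <- matrix(runif(n * n, 0, 255), n, n)
    phi <- matrix(rnorm(n * n, 0, 2), n, n)
    for (hard in c(FALSE, TRUE)) {
      p <- modelParams()
      expect_equal(updateMeans(img, phi, p, hard = hard),
                   oracleUpdateMeans(img, phi, p@epsilon, 1, hard = hard),
                   tolerance = 1e-9)
    }
  }
})

test_that("mean update recovers block means under a sharp membership", {
  s <- twoBlockImage(c(8, 8), 50, 200, noiseSigma = 0)
  phi <- matrix(-2, 8, 8); phi[, 1:4] <- 2      # left half positive
  mu <- updateMeans(intensities(s), phi, modelParams(epsilon = 1e-8))
  expect_equal(mu, c(50, 200), tolerance = 1e-6)
  muHard <- updateMeans(intensities(s), phi, modelParams(), hard = TRUE)
  expect_equal(muHard, c(50, 200))
})

test_that("mean update handles one-sided and constant inputs", {
  img <- matrix(c(1, 2, 3, 4), 2, 2)
  # everything positive with a sharp membership: class 2 is empty
  mu <- updateMeans(img, matrix(5, 2, 2), modelParams(epsilon = 1e-10))
  expect_equal(mu[1], mean(img), tolerance = 1e-6)
  expect_true(is.na(updateMeans(img, matrix(5, 2, 2), modelParams(),
                                hard = TRUE)[2]))
  # constant image: both means equal the constant whatever phi is
  phi <- matrix(rnorm(4), 2, 2)
  expect_equal(updateMeans(matrix(9, 2, 2), phi, modelParams()),
               c(9, 9), tolerance = 1e-9)
})

test_that("gradient flow step is stationary when forces vanish", {
  # equal class means make e1 = e2; with alpha = beta = 0 nothing moves
  img <- matrix(runif(64, 0, 255), 8, 8)
  phi <- matrix(rnorm(64), 8, 8)
  p <- modelParams(mu = c(100, 100), alpha = 0, beta = 0)
  expect_equal(gradientFlowStep(img, phi, p), phi)
})

test_that("distance regularization leaves a unit-slope plane untouched", {
  # border rows feel the replicated boundary; the regularizer diffuses that
  # ~3.6 px inward per iteration, so check well inside a larger grid
  n <- 64
  plane <- matrix(seq_len(n), n, n) - 32      # |grad phi| = 1
  img <- matrix(50, n, n)
  p <- modelParams(mu = c(50, 50), alpha = 0, beta = 0.001 * 255^2)
  out <- gradientFlowStep(img, plane, p)
  interior <- 28:(n - 27)
  expect_lt(max(abs((out - plane)[interior, interior])), 1e-6)
})

test_that("one flow step matches the scalar-loop oracle", {
  set.seed(13)
  for (n in c(8, 16)) {
    img <- matrix(runif(n * n, 0, 255), n, n)
    phi <- matrix(rnorm(n * n, 0, 2), n, n)
    p <- modelParams(mu = c(70, 180))
    got <- gradientFlowStep(img, phi, p)
    want <- oracleFlowStep(img, phi, 70, 180, p@alpha, p@beta, p@dt,
                           p@epsilon, 1)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("segmentation of a clean two-block image is exact", {
  s <- twoBlockImage(c(32, 32), 50, 200, noiseSigma = 0)
  r <- segmentVessels(s)
  expect_true(converged(r))
  expect_equal(sort(classMeans(r)), c(50, 200), tolerance = 1e-6)
  expect_equal(vesselMap(r), truthMap(s))
})

test_that("segmentation is deterministic", {
  s <- twoBlockImage(c(32, 32), 50, 200, noiseSigma = 5, seed = 4)
  r1 <- segmentVessels(s)
  r2 <- segmentVessels(s)
  expect_identical(vesselMap(r1), vesselMap(r2))
  expect_identical(levelSet(r1), levelSet(r2))
})

test_that("the result does not depend on the initial contour", {
  s <- twoBlockImage(c(48, 48), 50, 200, noiseSigma = 5, seed = 2)
  maps <- lapply(c("circle", "checkerboard", "otsu"), function(ini)
    vesselMap(segmentVessels(s, init = ini)))
  expect_identical(maps[[1]], maps[[2]])
  expect_identical(maps[[1]], maps[[3]])
})

test_that("negating the initial phi swaps labels but not the partition", {
  s <- twoBlockImage(c(32, 32), 50, 200, noiseSigma = 3, seed = 9)
  init <- levelSetInit(dim(intensities(s)), "circle")
  r1 <- segmentVessels(s, init = init)
  r2 <- segmentVessels(s, init = -init)
  expect_equal(sort(classMeans(r1)), sort(classMeans(r2)), tolerance = 1e-9)
  expect_equal(classMeans(r1), rev(classMeans(r2)), tolerance = 1e-9)
  expect_identical(vesselMap(r1), vesselMap(r2))   # vessel rule is label-free
})

test_that("class means are stationary at convergence", {
  s <- twoBlockImage(c(32, 32), 50, 200, noiseSigma = 5, seed = 6)
  r <- segmentVessels(s)
  recomputed <- updateMeans(intensities(s), levelSet(r), modelParams(),
                            hard = TRUE)
  expect_lt(max(abs(recomputed - classMeans(r))), 1e-6 * 255)
})

test_that("degenerate one-class input neither crashes nor invents vessels", {
  s <- twoBlockImage(c(24, 24), 100, 100, noiseSigma = 0)
  r <- segmentVessels(s)
  expect_s4_class(r, "SegmentationResult")
  expect_equal(classMeans(r), c(100, 100))
  # trivial partition: one side empty or the full frame
  expect_true(sum(vesselMap(r)) %in% c(0L, length(vesselMap(r))) ||
              converged(r))
})

test_that("vessel class mapping can be flipped", {
  s <- twoBlockImage(c(16, 16), 50, 200, noiseSigma = 0)
  dark <- segmentVessels(s, vesselClass = "darker")
  bright <- segmentVessels(s, vesselClass = "brighter")
  expect_identical(vesselMap(bright), !vesselMap(dark))
})

test_that("energy trace bookkeeping matches the iteration count", {
  s <- twoBlockImage(c(24, 24), 50, 200, noiseSigma = 2, seed = 3)
  r <- segmentVessels(s)
  expect_equal(nrow(energyTrace(r)), iterations(r))
  expect_named(energyTrace(r), c("data", "length", "regularization", "total"))
  expect_true(all(is.finite(as.matrix(energyTrace(r)))))
})
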