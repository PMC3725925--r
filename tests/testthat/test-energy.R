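test_that("energy density is the count-weighted squared deviation", {
  # constant image at the class mean: zero everywhere
  expect_equal(energyDensity(matrix(7, 5, 5), 7), matrix(0, 5, 5))
  # interior pixel of a 3x3 window: count 9
  e <- energyDensity(matrix(5, 5, 5), 2)
  expect_equal(e[3, 3], 9 * (5 - 2)^2)   # = 81
  # a 1x1 image only contains itself
  expect_equal(energyDensity(matrix(5, 1, 1), 2), matrix(9, 1, 1))
  expect_true(all(energyDensity(matrix(rnorm(16), 4, 4), 0.3) >= 0))
})

test_that("neighborhood counts match the brute-force double loop", {
  for (r in 1:2) for (center in c(TRUE, FALSE)) {
    spec <- neighborhoodSpec(radius = r, includeCenter = center)
    cnt <- neighborCount(c(6L, 7L), spec)
    expect_equal(cnt, oracleCount(6, 7, r, center))
    # interior count is the window size
    expect_equal(cnt[r + 2, r + 2], (2 * r + 1)^2 - !center)
    # double-count symmetry: sum_j c(j) = sum_i |N_i|
    expect_equal(sum(cnt), sum(oracleCount(6, 7, r, center)))
  }
})

test_that("energy operations match scalar-loop oracles on random fields", {
  set.seed(11)
  for (n in c(4, 9, 16)) {
    img <- matrix(runif(n * n, 0, 255), n, n)
    phi <- matrix(rnorm(n * n, 0, 3), n, n)
    p <- modelParams(mu = c(60, 190))
    expect_equal(energyDensity(img, 60, p@spec),
                 oracleEnergyDensity(img, 60, 1), tolerance = 1e-12)
    expect_equal(dataEnergy(img, phi, p),
                 oracleDataEnergy(img, phi, 60, 190, p@epsilon, 1),
                 tolerance = 1e-9)
    expect_equal(lengthEnergy(phi, 1.5), oracleLengthEnergy(phi, 1.5),
                 tolerance = 1e-9)
    expect_equal(distRegEnergy(phi), oracleDistRegEnergy(phi),
                 tolerance = 1e-9)
  }
})

test_that("data energy is symmetric under label swap", {
  set.seed(3)
  img <- matrix(runif(36, 0, 255), 6, 6)
  phi <- matrix(rnorm(36), 6, 6)
  a <- dataEnergy(img, phi, modelParams(mu = c(50, 200)))
  b <- dataEnergy(img, -phi, modelParams(mu = c(200, 50)))
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("data energy rejects mismatched shapes", {
  expect_error(dataEnergy(matrix(0, 4, 4), matrix(0, 3, 4),
                          modelParams(mu = c(0, 1))), "shape")
})

test_that("length energy of a constant field is zero", {
  expect_equal(lengthEnergy(matrix(3, 8, 8), 1), 0)
})

test_that("length energy recovers the circumference of a circle", {
  n <- 256; rad <- 60
  yy <- matrix(seq_len(n), n, n)
  xx <- matrix(seq_len(n), n, n, byrow = TRUE)
  phi <- rad - sqrt((yy - n / 2)^2 + (xx - n / 2)^2)  # signed distance
  expect_equal(lengthEnergy(phi, 1.5), 2 * pi * rad, tolerance = 0.05)
})

test_that("distance regularization vanishes on signed distance functions", {
  n <- 50
  plane <- matrix(seq_len(n), n, n) - 25.5         # |grad| = 1 along rows
  expect_lt(distRegEnergy(plane) / n^2, 1e-2)
  expect_equal(distRegEnergy(matrix(4, 5, 5)), 0.5 * 25)  # |grad| = 0
})

test_that("total energy assembles its terms with alpha and beta weights", {
  set.seed(8)
  img <- matrix(runif(64, 0, 255), 8, 8)
  phi <- matrix(rnorm(64, 0, 2), 8, 8)
  p <- modelParams(mu = c(80, 170), alpha = 0.7, beta = 12)
  eb <- totalEnergy(img, phi, p)
  expect_equal(eb@total,
               eb@dataTerm + 0.7 * eb@lengthTerm +
                 12 * eb@regularizationTerm, tolerance = 1e-9)
  expect_equal(eb@dataTerm, dataEnergy(img, phi, p))
  p0 <- modelParams(mu = c(80, 170), alpha = 0, beta = 0)
  expect_equal(totalEnergy(img, phi, p0)@total, dataEnergy(img, phi, p0))
})

test_that("data energy in mu is a parabola minimized at the closed-form mean", {
  set.seed(21)
  img <- matrix(runif(49, 0, 255), 7, 7)
  phi <- matrix(rnorm(49, 0, 2), 7, 7)
  p <- modelParams()
  mu <- updateMeans(img, phi, p)
  f <- function(m1) dataEnergy(img, phi, modelParams(mu = c(m1, 120)))
  expect_lt(f(mu[1]), f(mu[1] + 0.5))
  expect_lt(f(mu[1]), f(mu[1] - 0.5))
  # numerical minimum agrees with the closed form
  opt <- optimize(f, interval = c(0, 255))
  expect_equal(opt$minimum, mu[1], tolerance = 1e-4)
})
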