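test_that("rotation: identity at 0 and 360 degrees, centroid at 90 degrees", {
  set.seed(2)
  v <- interiorVolume(c(15L, 15L, 3L), margin = 4L)
  expect_identical(voxelData(rotateVolume(v, 0)), voxelData(v))
  r360 <- rotateVolume(v, 360)
  expect_lt(max(abs(voxelData(r360) - voxelData(v))) /
    max(voxelData(v)), 1e-6)

  ## centred point source rotated 90 deg CCW: (13, 9) -> (9, 13)
  pt <- array(0, c(17L, 17L, 1L))
  pt[13, 9, 1] <- 1
  r <- voxelData(rotateVolume(spectVolume(pt, 1), 90))[, , 1]
  cx <- sum(row(r) * r) / sum(r)
  cy <- sum(col(r) * r) / sum(r)
  expect_lt(abs(cx - 9), 0.5)
  expect_lt(abs(cy - 13), 0.5)
  expect_error(rotateVolume(v, NaN), "finite")
})

test_that("zero attenuation gives unit transmission everywhere", {
  z <- spectVolume(array(0, c(4L, 4L, 2L)), 1)
  expect_equal(attenuationFactors(z), array(1, c(4, 4, 2)))
})

test_that("attenuation column factors: closed-form exponential and scaling", {
  ## single column, uniform mu = 0.1/cm, 1 cm voxels, detector at +y:
  ## voxel nearest the detector (iy = ny) has factor exp(-0.05)
  ny <- 6L
  mu <- spectVolume(array(0.1, c(1L, ny, 1L)), 1)
  f <- attenuationFactors(mu)[1, , 1]
  expect_equal(f[ny], exp(-0.05), tolerance = 1e-12)
  ## voxel iy sees (ny - iy) full voxels plus its half voxel
  expect_equal(f, exp(-(0.1 * (ny - seq_len(ny)) + 0.05)),
    tolerance = 1e-12)
  ## doubling mu squares every factor
  f2 <- attenuationFactors(spectVolume(array(0.2, c(1L, ny, 1L)), 1))[1, , 1]
  expect_equal(f2, f^2, tolerance = 1e-12)
  expect_error(attenuationFactors(spectVolume(array(c(0.1, -0.1),
    c(2, 1, 1)), 1)), "non-negative")
})

test_that("gaussian diffusion step: identity, second moment, semigroup", {
  p <- matrix(runif(33 * 33), 33)
  expect_identical(gaussianDiffusionStep(p, 0, 1), p)
  expect_error(gaussianDiffusionStep(p, -1, 1), ">= 0")

  delta <- matrix(0, 33, 33); delta[17, 17] <- 1
  for (sig in c(1, 2)) {
    out <- gaussianDiffusionStep(delta, sig, 1)
    prof <- rowSums(out)
    m <- sum((1:33) * prof) / sum(prof)
    v <- sum(((1:33) - m)^2 * prof) / sum(prof)
    expect_equal(v, sig^2, tolerance = 0.01)
    expect_equal(sum(out), 1, tolerance = 1e-6)
  }
  ## chaining sigma1 then sigma2 ~ one blur of sqrt(s1^2 + s2^2)
  chained <- gaussianDiffusionStep(gaussianDiffusionStep(delta, 1, 1),
    1.5, 1)
  oneShot <- gaussianDiffusionStep(delta, sqrt(1 + 1.5^2), 1)
  expect_lt(max(abs(chained - oneShot)) / max(oneShot), 0.01)
})

test_that("forward projection of a slab is its line integral; counts conserve per angle", {
  gd <- c(16L, 16L, 4L)
  geom <- testGeometry(gd, nAngles = 8)
  noColl <- collimatorModel(enabled = FALSE)
  ## single-voxel-thick slab of activity A: bins under it read A
  slab <- array(0, gd)
  slab[5:12, 8, 2] <- 3
  p <- forwardProject(spectVolume(slab, 1), geom, noColl)
  p0 <- projectionData(p)[, , 1]    # angle 0: detector along +y
  expect_equal(p0[5:12, 2], rep(3, 8), tolerance = 1e-12)
  expect_equal(sum(p0[-(5:12), ]), 0)

  ## count conservation at every angle for interior content
  set.seed(3)
  v <- interiorVolume(gd, margin = 4L)
  pv <- forwardProject(v, geom, noColl)
  sums <- apply(projectionData(pv), 3, sum)
  expect_lt(max(abs(sums - sum(voxelData(v)))) / sum(voxelData(v)),
    0.001)
})

test_that("point-source projection width matches the distance-dependent PSF", {
  gd <- c(33L, 33L, 17L)
  geom <- acquisitionGeometry(nAngles = 2, orbitRadiusCm = 30,
    detectorBins = 33, detectorRows = 17, binSizeCm = 1)
  coll <- collimatorModel(sigma0Cm = 0.5, slope = 0.08)
  src <- array(0, gd); src[17, 17, 9] <- 1
  p <- forwardProject(spectVolume(src, 1), geom, coll)
  ## source on the rotation axis: distance = orbit radius at every angle
  for (k in 1:2) {
    prof <- rowSums(p@data[, , k])
    m <- sum((1:33) * prof) / sum(prof)
    s <- sqrt(sum(((1:33) - m)^2 * prof) / sum(prof))
    expect_equal(s, psfSigma(coll, 30), tolerance = 0.1)
  }
})

test_that("cumulative plane-by-plane diffusion matches a one-shot blur of sigma(d)", {
  ## a single far plane swept through the whole volume must come out
  ## blurred by sigma(d_plane) as if blurred once
  gd <- c(33L, 33L, 17L)
  geom <- acquisitionGeometry(nAngles = 1, orbitRadiusCm = 25,
    detectorBins = 33, detectorRows = 17, binSizeCm = 1)
  coll <- collimatorModel(sigma0Cm = 0.4, slope = 0.06)
  m <- systemModel(gd, c(1, 1, 1), geom, coll)
  src <- array(0, gd)
  src[17, 2, 9] <- 1                      # iy = 2: nearly farthest plane
  p <- BayesSPECT:::.forwardArr(m, src, 1L)[, , 1]
  d <- m@cache$planeDistCm[2]
  oneShot <- gaussianDiffusionStep(matrix(src[, 2, ], 33, 17),
    psfSigma(coll, d), 1)
  expect_lt(max(abs(p - oneShot)) / max(oneShot), 0.01)
})

test_that("back projection is the exact adjoint, with and without attenuation/collimator", {
  set.seed(4)
  gd <- c(16L, 16L, 8L)
  geom <- testGeometry(gd, nAngles = 12)
  mu <- spectVolume(array(runif(prod(gd), 0, 0.05), gd), 1)
  cases <- list(
    list(coll = collimatorModel(enabled = FALSE), mu = NULL),
    list(coll = collimatorModel(0.3, 0.05), mu = NULL),
    list(coll = collimatorModel(enabled = FALSE), mu = mu),
    list(coll = collimatorModel(0.3, 0.05), mu = mu))
  for (cs in cases) {
    m <- systemModel(gd, c(1, 1, 1), geom, cs$coll, cs$mu)
    x <- array(runif(prod(gd)), gd)
    y <- array(runif(gd[1] * gd[3] * 12), c(gd[1], gd[3], 12))
    Ax <- BayesSPECT:::.forwardArr(m, x, 1:12)
    Aty <- BayesSPECT:::.backArr(m, y, 1:12)
    expect_lt(abs(sum(Ax * y) - sum(x * Aty)) / sum(Ax * y), 1e-6)
  }
})

test_that("back projection of ones gives the sensitivity; zeros give zero", {
  gd <- c(12L, 12L, 4L)
  geom <- testGeometry(gd, nAngles = 6)
  m <- systemModel(gd, c(1, 1, 1), geom, collimatorModel(enabled = FALSE))
  ones <- projectionSet(array(1, c(12, 4, 6)), geom)
  sens <- backProject(ones, model = m)
  sensRef <- sensitivityImage(m, 1:6)
  expect_equal(voxelData(sens), voxelData(sensRef))
  ## interior sensitivity ~ one count per angle per voxel
  expect_equal(mean(voxelData(sens)[5:8, 5:8, 2]), 6, tolerance = 0.05)
  zeros <- projectionSet(array(0, c(12, 4, 6)), geom)
  expect_equal(voxelData(backProject(zeros, model = m)),
    array(0, gd))
  expect_error(backProject(ones, model = m, subset = integer(0)),
    "non-empty")
  expect_error(backProject(ones, model = m, subset = 99), "invalid")
})

test_that("increasing attenuation never increases any projection value", {
  set.seed(5)
  gd <- c(12L, 12L, 4L)
  geom <- testGeometry(gd, nAngles = 8)
  coll <- collimatorModel(0.3, 0.04)
  act <- interiorVolume(gd, margin = 3L)
  mu1 <- spectVolume(array(runif(prod(gd), 0, 0.03), gd), 1)
  mu2 <- spectVolume(voxelData(mu1) + 0.02, 1)   # raised everywhere
  p1 <- forwardProject(act, geom, coll, mu1)
  p2 <- forwardProject(act, geom, coll, mu2)
  expect_true(all(projectionData(p2) <= projectionData(p1) + 1e-12))
})

test_that("disabling the collimator model reproduces the NORR projector exactly", {
  set.seed(6)
  gd <- c(12L, 12L, 4L)
  geom <- testGeometry(gd, nAngles = 4)
  act <- interiorVolume(gd, margin = 3L)
  pDisabled <- forwardProject(act, geom, collimatorModel(0.3, 0.05,
    enabled = FALSE))
  pZero <- forwardProject(act, geom, collimatorModel(0, 0,
    enabled = FALSE))
  expect_identical(projectionData(pDisabled), projectionData(pZero))
})

test_that("system model rejects inconsistent geometry", {
  geom <- acquisitionGeometry(nAngles = 4, orbitRadiusCm = 20,
    detectorBins = 10, detectorRows = 4, binSizeCm = 1)
  expect_error(systemModel(c(12, 12, 4), 1, geom, collimatorModel()),
    "does not match")
  geom2 <- acquisitionGeometry(nAngles = 4, orbitRadiusCm = 20,
    detectorBins = 12, detectorRows = 4, binSizeCm = 0.5)
  expect_error(systemModel(c(12, 12, 4), 1, geom2, collimatorModel()),
    "bin size")
})
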