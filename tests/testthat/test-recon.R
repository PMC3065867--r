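test_that("makeSubsets partitions angles with maximal stride", {
  s <- makeSubsets(128, 16)
  expect_s4_class(s, "SubsetScheme")
  expect_length(s@subsets, 16)
  for (sub in s@subsets) {
    expect_length(sub, 8)
    expect_true(all(diff(sub) == 16))
  }
  expect_setequal(unlist(s@subsets), 1:128)
  ## bit-reversed processing order separates consecutive subsets
  firsts <- vapply(s@subsets, `[`, 1L, 1L)
  expect_equal(firsts[1:4], c(1L, 9L, 5L, 13L))

  s1 <- makeSubsets(8, 1)
  expect_identical(s1@subsets[[1]], 1:8)
  expect_error(makeSubsets(8, 3), "valid choices: 1, 2, 4, 8")
})

test_that("OSEM update matches brute-force evaluation with the enumerated system matrix", {
  set.seed(11)
  gd <- c(8L, 8L, 2L)
  geom <- testGeometry(gd, nAngles = 4)
  m <- systemModel(gd, c(1, 1, 1), geom, collimatorModel(0.3, 0.05),
    spectVolume(array(0.02, gd), 1))
  A <- denseSystemMatrix(m, 1:4)          # independent dense oracle
  fOld <- array(runif(prod(gd), 0.5, 2), gd)
  pTrue <- array(runif(gd[1] * gd[3] * 4, 0, 5), c(gd[1], gd[3], 4))
  subset <- c(2L, 4L)
  rows <- as.numeric(outer(seq_len(gd[1] * gd[3]),
    (subset - 1) * gd[1] * gd[3], "+"))
  As <- A[rows, ]
  q <- As %*% as.numeric(fOld)
  sens <- colSums(As)
  fRef <- as.numeric(fOld) / sens * as.numeric(t(As) %*%
    (as.numeric(pTrue[, , subset]) / q))
  fNew <- osemUpdate(spectVolume(fOld, 1),
    projectionSet(pTrue, geom), subset, m)
  expect_equal(as.numeric(voxelData(fNew)), fRef, tolerance = 1e-10)
})

test_that("OSEM fixed point and degenerate inputs", {
  std <- smallSphereStudy(counts = 1e6)
  gd <- dim(voxelData(std$phantom$activity))
  m <- systemModel(gd, voxelSpacing(std$phantom$activity),
    std$geometry, std$collimator, std$phantom$mu)
  ## noiseless data from the truth: the truth is a fixed point
  truth <- std$phantom$activity
  pNoiseless <- forwardProject(truth, model = m)
  f1 <- osemUpdate(truth, pNoiseless, 1:8, m)
  rel <- abs(voxelData(f1) - voxelData(truth)) /
    max(voxelData(truth))
  expect_lt(max(rel), 1e-6)
  ## zero measured counts zero the image
  pZero <- projectionSet(array(0, dim(projectionData(pNoiseless))),
    std$geometry)
  f0 <- osemUpdate(spectVolume(array(1, gd),
    voxelSpacing(truth)), pZero, 1:8, m)
  expect_equal(max(voxelData(f0)), 0)
  ## negative inputs rejected
  expect_error(osemUpdate(spectVolume(array(-1, gd), voxelSpacing(truth)),
    pNoiseless, 1:8, m), "non-negative")
})

test_that("OSL with beta = 0 or prior none is bitwise identical to OSEM", {
  std <- smallSphereStudy()
  gd <- dim(voxelData(std$phantom$activity))
  m <- systemModel(gd, voxelSpacing(std$phantom$activity),
    std$geometry, std$collimator, std$phantom$mu)
  f <- spectVolume(array(runif(prod(gd), 0.1, 1), gd),
    voxelSpacing(std$phantom$activity))
  ref <- osemUpdate(f, std$projections, 1:8, m)
  for (pr in list(priorConfig("smooth", beta = 0),
      priorConfig("mrp", beta = 0),
      priorConfig("none", beta = 0.3))) {
    osl <- oslUpdate(f, std$projections, 1:8, m, pr)
    expect_identical(voxelData(osl), voxelData(ref))
  }
})

test_that("all update outputs stay non-negative", {
  std <- smallSphereStudy()
  gd <- dim(voxelData(std$phantom$activity))
  sp <- voxelSpacing(std$phantom$activity)
  m <- systemModel(gd, sp, std$geometry, std$collimator,
    std$phantom$mu)
  set.seed(12)
  for (pr in list(priorConfig("none"), priorConfig("smooth", beta = 2),
      priorConfig("mrp", beta = 2))) {
    f <- spectVolume(array(runif(prod(gd), 0, 2), gd) *
      rbinom(prod(gd), 1, 0.8), sp)
    out <- oslUpdate(f, std$projections, 1:8, m, pr)
    expect_true(all(voxelData(out) >= 0))
  }
})

test_that("MLEM log-likelihood is non-decreasing on noisy and noiseless data", {
  std <- smallSphereStudy(gridDim = c(24L, 24L, 4L), voxelSizeCm = 1.25,
    nAngles = 16, counts = 2e5)
  cfg <- reconConfig(nIterations = 20, nSubsets = 1,
    prior = priorConfig("none"), collimator = std$collimator,
    attenuation = std$phantom$mu)
  for (noisy in c(TRUE, FALSE)) {
    p <- if (noisy) std$projections else
      forwardProject(std$phantom$activity, std$geometry,
        std$collimator, std$phantom$mu)
    r <- runReconstruction(p, cfg)
    ll <- reconLog(r)$logLik
    expect_true(all(diff(ll) > -1e-6 * abs(ll[-1])))
  }
})

test_that("runReconstruction honours configuration and logs records", {
  std <- smallSphereStudy()
  cfgOsem <- reconConfig(nIterations = 2, nSubsets = 8,
    prior = priorConfig("none"), collimator = std$collimator,
    attenuation = std$phantom$mu)
  r <- runReconstruction(std$projections, cfgOsem)
  lg <- reconLog(r)
  expect_equal(nrow(lg), 16)
  expect_true(all(lg$minVoxel >= 0))
  expect_false(any(is.na(lg$logLik[lg$subset == 8])))
  ## beta = 0 OSL run identical to the OSEM run
  cfgOsl <- reconConfig(nIterations = 2, nSubsets = 8,
    prior = priorConfig("smooth", beta = 0),
    collimator = std$collimator, attenuation = std$phantom$mu)
  r2 <- runReconstruction(std$projections, cfgOsl)
  expect_identical(voxelData(reconVolume(r2)),
    voxelData(reconVolume(r)))
  ## post-filter applied when configured
  cfgPf <- reconConfig(nIterations = 1, nSubsets = 8,
    prior = priorConfig("none"), collimator = std$collimator,
    attenuation = std$phantom$mu, postfilterFwhmCm = 1.88)
  rp <- runReconstruction(std$projections, cfgPf)
  expect_lt(max(voxelData(reconVolume(rp))), max(voxelData(reconVolume(
    runReconstruction(std$projections, reconConfig(nIterations = 1,
      nSubsets = 8, prior = priorConfig("none"),
      collimator = std$collimator, attenuation = std$phantom$mu))))))
})
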