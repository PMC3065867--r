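sensOf <- function(gd, value = 4) spectVolume(array(value, gd), 1)

test_that("smoothing penalty is neutral on uniform images and matches a brute-force reference", {
  gd <- c(8L, 8L, 8L)
  pr <- priorConfig("smooth", beta = 0.3)
  sens <- sensOf(gd)
  ## uniform image: A_j = f_j, penalty term zero, c^P = 1/sensitivity
  u <- spectVolume(array(5, gd), 1)
  cP <- smoothingPenaltyFactor(u, pr, sens)
  expect_equal(voxelData(cP), array(0.25, gd), tolerance = 1e-14)

  ## random image: matches the naive triple-loop evaluation exactly
  set.seed(21)
  f <- spectVolume(array(runif(prod(gd), 0.1, 3), gd), 1)
  nb <- BayesSPECT:::.neighbourOffsets(3L, c(1, 1, 1))
  A <- naiveNeighbourMean(voxelData(f), nb$offsets, nb$weights)
  cRef <- 1 / (voxelData(sens) + 0.3 * (voxelData(f) - A) / pmax(A, 1e-12))
  cP2 <- smoothingPenaltyFactor(f, pr, sens)
  expect_lt(max(abs(voxelData(cP2) - cRef)), 1e-12)

  ## single hot centre in a 3x3x3 block: closed-form inverse-distance mean
  g3 <- c(3L, 3L, 3L)
  fb <- array(1, g3); fb[2, 2, 2] <- 10
  nb3 <- BayesSPECT:::.neighbourOffsets(3L, c(1, 1, 1))
  ACentre <- sum(nb3$weights * 1) / sum(nb3$weights)   # all neighbours 1
  cB <- smoothingPenaltyFactor(spectVolume(fb, 1), pr, sensOf(g3))
  expect_equal(voxelData(cB)[2, 2, 2],
    1 / (4 + 0.3 * (10 - ACentre) / ACentre), tolerance = 1e-12)
})

test_that("median root prior: neutral on uniform and locally monotonic images, matches brute force", {
  gd <- c(8L, 8L, 8L)
  pr <- priorConfig("mrp", beta = 0.3)
  sens <- sensOf(gd)
  u <- spectVolume(array(5, gd), 1)
  expect_equal(voxelData(mrpPenaltyFactor(u, pr, sens)),
    array(0.25, gd), tolerance = 1e-14)

  ## locally monotonic ramp: interior medians equal the centre value
  ramp <- array(rep(seq_len(gd[1]), times = prod(gd[2:3])), gd)
  cP <- mrpPenaltyFactor(spectVolume(ramp, 1), pr, sens)
  interior <- voxelData(cP)[2:7, 2:7, 2:7]
  expect_equal(interior, array(0.25, c(6, 6, 6)), tolerance = 1e-14)

  ## median of 1..27 in a 3^3 window is 14
  g3 <- c(3L, 3L, 3L)
  f27 <- array(1:27, g3)
  M <- array(BayesSPECT:::.cppMedianFilter3(as.numeric(f27),
    as.integer(g3), 3L), g3)
  expect_equal(M[2, 2, 2], 14)
  cRef <- 1 / (4 + 0.3 * (f27 - M) / pmax(M, 1e-12))
  expect_equal(voxelData(mrpPenaltyFactor(spectVolume(f27, 1), pr,
    sensOf(g3))), cRef, tolerance = 1e-14)

  ## full window median (borders truncated) matches the naive reference
  set.seed(22)
  f <- array(runif(prod(gd)), gd)
  Mfast <- array(BayesSPECT:::.cppMedianFilter3(as.numeric(f),
    as.integer(gd), 3L), gd)
  expect_equal(Mfast, naiveMedianFilter(f, 3L), tolerance = 1e-15)
})

test_that("Bowsher selection: uniform anatomy, step edges, and B = scan count", {
  gd <- c(6L, 6L, 6L)
  ## uniform anatomy: every interior voxel keeps the B closest offsets
  ## under the (distance, lexicographic) tie-break, identically
  prU <- priorConfig("bowsher", beta = 0.3, bowsherB = 9,
    anatomical = spectVolume(array(7, gd), 1))
  selU <- bowsherSelect(prU@anatomical, prU)
  nb <- BayesSPECT:::.neighbourOffsets(3L, c(1, 1, 1))
  expect_equal(selU@offsets, nb$offsets[1:18, ])
  interior <- which(array(TRUE, gd) &
    BayesSPECT:::.shiftArr(array(1, gd), c(0, 0, 0)) > 0)
  centre <- 2 + 6 * (2 + 6 * 2) + 1   # voxel (3,4,3): fully interior
  expect_equal(which(selU@selection[centre, ] == 1), 1:9)
  ## identical selection at all fully interior voxels
  inner <- as.numeric(which(BayesSPECT:::.shiftArr(array(1, gd),
    c(1, 1, 1)) * BayesSPECT:::.shiftArr(array(1, gd),
    c(-1, -1, -1)) > 0))
  sels <- selU@selection[inner, , drop = FALSE]
  expect_true(all(apply(sels, 1, identical, sels[1, ])))

  ## anatomical step edge in x: selection never crosses the edge when
  ## enough same-side candidates exist
  anat <- array(0, gd); anat[4:6, , ] <- 100
  prE <- priorConfig("bowsher", beta = 0.3, bowsherB = 6,
    anatomical = spectVolume(anat, 1))
  selE <- bowsherSelect(prE@anatomical, prE)
  ## voxel (3, 3, 3) sits on the low side; selected offsets must have
  ## x + ox <= 3 (the high side differs by 100)
  v <- 3 + 6 * (2 + 6 * 2)
  chosen <- selE@offsets[selE@selection[v, ] == 1, , drop = FALSE]
  expect_true(all(3 + chosen[, 1] <= 3))
  expect_equal(nrow(chosen), 6)

  ## B = scan count keeps the whole scanned neighbourhood
  prAll <- priorConfig("bowsher", beta = 0.3, bowsherScan = 18,
    bowsherB = 18, anatomical = spectVolume(array(7, gd), 1))
  selAll <- bowsherSelect(prAll@anatomical, prAll)
  valid <- selAll@selection[centre, ]
  expect_equal(sum(valid), 18)

  ## border voxels keep all available candidates
  corner <- 1
  expect_lt(sum(selE@selection[corner, ]), 7)
  expect_gt(sum(selE@selection[corner, ]), 0)
})

test_that("Bowsher penalty reduces to the smoothing prior for uniform anatomy and B = scan count", {
  gd <- c(8L, 8L, 8L)
  set.seed(23)
  f <- spectVolume(array(runif(prod(gd), 0.1, 3), gd), 1)
  sens <- sensOf(gd)
  pr <- priorConfig("bowsher", beta = 0.3, bowsherScan = 18,
    bowsherB = 18, anatomical = spectVolume(array(1, gd), 1))
  sel <- bowsherSelect(pr@anatomical, pr)
  cB <- bowsherPenaltyFactor(f, pr, sel, sens)
  ## smoothing prior restricted to the 18 scanned offsets
  nb <- BayesSPECT:::.neighbourOffsets(3L, c(1, 1, 1))
  A <- naiveNeighbourMean(voxelData(f), nb$offsets[1:18, ],
    nb$weights[1:18])
  cRef <- 1 / (4 + 0.3 * (voxelData(f) - A) / pmax(A, 1e-12))
  expect_lt(max(abs(voxelData(cB) - cRef)), 1e-12)

  ## uniform image: c^P = 1/sensitivity regardless of anatomy
  u <- spectVolume(array(2, gd), 1)
  prAnat <- priorConfig("bowsher", beta = 0.3,
    anatomical = spectVolume(array(runif(prod(gd)), gd), 1))
  selA <- bowsherSelect(prAnat@anatomical, prAnat)
  expect_equal(voxelData(bowsherPenaltyFactor(u, prAnat, selA, sens)),
    array(0.25, gd), tolerance = 1e-14)
})

test_that("Bowsher penalty matches the naive per-voxel selected sum near an anatomical edge", {
  gd <- c(8L, 8L, 8L)
  anat <- array(0, gd); anat[5:8, , ] <- 100
  pr <- priorConfig("bowsher", beta = 0.3,
    anatomical = spectVolume(anat, 1))
  sel <- bowsherSelect(pr@anatomical, pr)
  set.seed(24)
  f <- spectVolume(array(runif(prod(gd), 0.1, 2), gd), 1)
  sens <- sensOf(gd)
  A <- naiveNeighbourMean(voxelData(f), sel@offsets, sel@weights,
    selMat = sel@selection)
  cRef <- 1 / (4 + 0.3 * (voxelData(f) - A) / pmax(A, 1e-12))
  expect_lt(max(abs(voxelData(bowsherPenaltyFactor(f, pr, sel, sens)) -
    cRef)), 1e-12)
})

test_that("prior configuration invariants are enforced", {
  expect_error(priorConfig("smooth", beta = -1), "beta")
  expect_error(priorConfig("mrp", neighbourhood = 4), "odd")
  expect_error(priorConfig("bowsher", bowsherScan = 30, bowsherB = 40),
    "bowsherB")
  expect_error(priorConfig("bowsher"), "anatomical")
})
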