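# Shared fixtures: everything is generated in code at test time.

# small acquisition matched to a grid (bins = nx, rows = nz)
testGeometry <- function(gridDim, nAngles = 16, orbitRadiusCm = 20,
    binSizeCm = 1) {
  acquisitionGeometry(nAngles = nAngles, orbitRadiusCm = orbitRadiusCm,
    detectorBins = gridDim[1], detectorRows = gridDim[3],
    binSizeCm = binSizeCm)
}

# random non-negative volume supported away from the in-plane borders
# (and, with zMargin, away from the axial borders too)
interiorVolume <- function(gridDim, margin = 3L, spacing = 1,
    zMargin = 0L) {
  a <- array(0, gridDim)
  ix <- (margin + 1):(gridDim[1] - margin)
  iy <- (margin + 1):(gridDim[2] - margin)
  iz <- (zMargin + 1):(gridDim[3] - zMargin)
  a[ix, iy, iz] <- runif(length(ix) * length(iy) * length(iz))
  spectVolume(a, spacing)
}

# dense system matrix by brute-force enumeration: forward projection of
# every unit voxel (independent oracle for the update equations)
denseSystemMatrix <- function(model, angleIdx) {
  d <- model@dims
  nvox <- prod(d)
  nproj <- d[1] * d[3] * length(angleIdx)
  A <- matrix(0, nproj, nvox)
  for (j in seq_len(nvox)) {
    e <- array(0, d)
    e[j] <- 1
    A[, j] <- as.numeric(BayesSPECT:::.forwardArr(model, e, angleIdx))
  }
  A
}

# naive triple-loop weighted neighbourhood mean (reference for the
# penalty-factor implementations); selFun(centreIdx3, offsetRow) optionally
# restricts the offsets used at each voxel
naiveNeighbourMean <- function(fArr, offsets, weights, selMat = NULL) {
  d <- dim(fArr)
  out <- fArr
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    num <- 0; den <- 0
    j <- x + d[1] * ((y - 1) + d[2] * (z - 1))
    for (k in seq_len(nrow(offsets))) {
      xx <- x + offsets[k, 1]; yy <- y + offsets[k, 2]
      zz <- z + offsets[k, 3]
      if (xx < 1 || xx > d[1] || yy < 1 || yy > d[2] ||
          zz < 1 || zz > d[3]) next
      if (!is.null(selMat) && selMat[j, k] == 0) next
      num <- num + weights[k] * fArr[xx, yy, zz]
      den <- den + weights[k]
    }
    if (den > 0) out[x, y, z] <- num / den
  }
  out
}

# naive median over the truncated cubic window, centre included
naiveMedianFilter <- function(fArr, w) {
  d <- dim(fArr)
  r <- (w - 1) / 2
  out <- fArr
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    xs <- max(1, x - r):min(d[1], x + r)
    ys <- max(1, y - r):min(d[2], y + r)
    zs <- max(1, z - r):min(d[3], z + r)
    out[x, y, z] <- median(fArr[xs, ys, zs])
  }
  out
}

# tiny hot-sphere phantom + acquisition for reconstruction tests
smallSphereStudy <- function(gridDim = c(32L, 32L, 8L),
    voxelSizeCm = 0.94, nAngles = 32L, counts = 2e5, seed = 7L,
    collimator = collimatorModel()) {
  ph <- buildSpherePhantom(spherePhantomSpec(gridDim = gridDim,
    voxelSizeCm = voxelSizeCm))
  geom <- acquisitionGeometry(nAngles = nAngles, orbitRadiusCm = 24,
    detectorBins = gridDim[1], detectorRows = gridDim[3],
    binSizeCm = voxelSizeCm)
  proj <- simulateAcquisition(ph$activity, ph$mu, geom, collimator,
    counts, seed = seed)
  list(phantom = ph, geometry = geom, projections = proj,
    collimator = collimator)
}
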