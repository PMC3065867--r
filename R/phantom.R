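## Digital phantoms: a hot-sphere cylinder phantom (five spheres of
## graded diameter in a water-filled body) and a rod phantom with
## hot/cold/uniform cylindrical inserts, each returning matched activity,
## attenuation and anatomical volumes plus the ground-truth geometry.
## Voxels straddling boundaries receive partial-volume fractions by
## supersampling.

## CT-like values used for the synthetic anatomical volumes (HU).
## Sphere interiors are water-filled and indistinguishable from the body
## on CT; the glass shells are the distinct structure (a thin dense ring),
## as on a low-dose CT of the physical insert.
.HU_AIR <- -1000
.HU_WATER <- 0
.HU_SHELL <- 300
.HU_ROD <- 120
.SHELL_THICKNESS_CM <- 0.2

#' Specification of the hot-sphere phantom
#'
#' A water-filled cylindrical body containing hot spheres of graded
#' diameter mounted on a ring. Defaults emulate a commercial hot-sphere
#' quality-control insert: 23.6 cm body, sphere diameters 10, 17, 22, 28
#' and 37 mm, zero background activity, spheres on a ring at 60% of the
#' body radius in order of size.
#'
#' @param bodyDiameterCm outer body diameter (cm).
#' @param sphereDiametersMm active sphere diameters (mm).
#' @param sphereActivity activity concentration inside the spheres
#'   (arbitrary units/voxel at unit voxel volume).
#' @param backgroundActivity body background concentration.
#' @param ringRadiusFraction sphere-ring radius as a fraction of the body
#'   radius.
#' @param ringStartAngleDeg angular position of the largest sphere.
#' @param voxelSizeCm isotropic voxel size (cm).
#' @param gridDim integer(3) grid dimensions.
#' @param supersample per-axis subdivision for partial-volume fractions.
#' @return A list of class \code{"spherePhantomSpec"}.
#' @export
spherePhantomSpec <- function(bodyDiameterCm = 23.6,
    sphereDiametersMm = c(10, 17, 22, 28, 37), sphereActivity = 1,
    backgroundActivity = 0, ringRadiusFraction = 0.6,
    ringStartAngleDeg = 90, voxelSizeCm = 0.47,
    gridDim = c(64L, 64L, 32L), supersample = 3L) {
  structure(list(bodyDiameterCm = bodyDiameterCm,
    sphereDiametersMm = sphereDiametersMm,
    sphereActivity = sphereActivity,
    backgroundActivity = backgroundActivity,
    ringRadiusFraction = ringRadiusFraction,
    ringStartAngleDeg = ringStartAngleDeg, voxelSizeCm = voxelSizeCm,
    gridDim = as.integer(gridDim), supersample = as.integer(supersample)),
    class = "spherePhantomSpec")
}

#' Specification of the rod (lesion-resolution) phantom
#'
#' A water tank with axial cylindrical rods: a hot-rod set, a cold-rod
#' set, or a uniform tank for homogeneity tests. Default diameters follow
#' a commercial lesion-resolution insert.
#'
#' @param tankDiameterCm inner tank diameter (cm).
#' @param hotRodDiametersMm hot-rod diameters (mm).
#' @param coldRodDiametersMm cold-rod diameters (mm).
#' @param mode "hot", "cold" or "uniform".
#' @param rodActivity concentration inside hot rods.
#' @param backgroundActivity tank concentration (cold/uniform modes).
#' @param ringRadiusFraction rod-ring radius as a fraction of the tank
#'   radius.
#' @param voxelSizeCm isotropic voxel size (cm).
#' @param gridDim integer(3) grid dimensions.
#' @param supersample per-axis subdivision for partial-volume fractions.
#' @return A list of class \code{"rodPhantomSpec"}.
#' @export
rodPhantomSpec <- function(tankDiameterCm = 21.5,
    hotRodDiametersMm = c(4.7, 5.9, 7.3, 9.2, 11.4, 14.3, 17.9, 22.3),
    coldRodDiametersMm = c(5.9, 7.3, 9.2, 11.4, 14.3, 17.9, 22.3),
    mode = c("hot", "cold", "uniform"), rodActivity = 1,
    backgroundActivity = 1, ringRadiusFraction = 0.55,
    voxelSizeCm = 0.47, gridDim = c(64L, 64L, 32L), supersample = 3L) {
  structure(list(tankDiameterCm = tankDiameterCm,
    hotRodDiametersMm = hotRodDiametersMm,
    coldRodDiametersMm = coldRodDiametersMm, mode = match.arg(mode),
    rodActivity = rodActivity, backgroundActivity = backgroundActivity,
    ringRadiusFraction = ringRadiusFraction, voxelSizeCm = voxelSizeCm,
    gridDim = as.integer(gridDim), supersample = as.integer(supersample)),
    class = "rodPhantomSpec")
}

## centred physical coordinates of voxel centres along one axis
.axisCoords <- function(n, dx) (seq_len(n) - (n + 1) / 2) * dx

## per-voxel inside-fraction of a sphere, by supersampling
.sphereFrac <- function(gridDim, dx, centre, radius, super) {
  xs <- .axisCoords(gridDim[1], dx)
  ys <- .axisCoords(gridDim[2], dx)
  zs <- .axisCoords(gridDim[3], dx)
  sub <- (seq_len(super) - (super + 1) / 2) / super * dx
  frac <- array(0, gridDim)
  ## restrict to the bounding box (one-voxel margin)
  ix <- which(abs(xs - centre[1]) <= radius + dx)
  iy <- which(abs(ys - centre[2]) <= radius + dx)
  iz <- which(abs(zs - centre[3]) <= radius + dx)
  if (!length(ix) || !length(iy) || !length(iz)) return(frac)
  acc <- array(0, c(length(ix), length(iy), length(iz)))
  for (ox in sub) for (oy in sub) for (oz in sub) {
    dx2 <- (xs[ix] + ox - centre[1])^2
    dy2 <- (ys[iy] + oy - centre[2])^2
    dz2 <- (zs[iz] + oz - centre[3])^2
    acc <- acc + (outer(outer(dx2, dy2, "+"), dz2, "+") <= radius^2)
  }
  frac[ix, iy, iz] <- acc / super^3
  frac
}

## per-voxel inside-fraction of an axial cylinder (full z extent),
## supersampled in-plane
.cylinderFrac <- function(gridDim, dx, centre, radius, super) {
  xs <- .axisCoords(gridDim[1], dx)
  ys <- .axisCoords(gridDim[2], dx)
  sub <- (seq_len(super) - (super + 1) / 2) / super * dx
  acc <- matrix(0, gridDim[1], gridDim[2])
  for (ox in sub) for (oy in sub)
    acc <- acc + (outer((xs + ox - centre[1])^2,
      (ys + oy - centre[2])^2, "+") <= radius^2)
  array(acc / super^2, gridDim)
}

.checkInsertLayout <- function(centres, radii, containerRadius, what) {
  n <- nrow(centres)
  for (i in seq_len(n)) {
    if (sqrt(sum(centres[i, 1:2]^2)) + radii[i] > containerRadius)
      stop(what, " ", i, " extends outside the phantom body",
        call. = FALSE)
    if (i < n) for (j in (i + 1):n) {
      if (sqrt(sum((centres[i, ] - centres[j, ])^2)) <
          radii[i] + radii[j])
        stop(what, "s ", i, " and ", j, " overlap", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Build the hot-sphere phantom volumes
#'
#' @param spec a [spherePhantomSpec()].
#' @return A list with elements \code{activity}, \code{mu} (water
#'   attenuation inside the body, 1/cm), \code{anatomical} (CT-like HU:
#'   air -1000, body water 0, thin dense sphere shells) — all
#'   [SpectVolume-class] on the same grid — and \code{geometry}, a
#'   data.frame of the true sphere centres (cm, centred coordinates) and
#'   diameters, largest first.
#' @examples
#' ph <- buildSpherePhantom(spherePhantomSpec(gridDim = c(32, 32, 8),
#'   voxelSizeCm = 0.94))
#' ph$geometry
#' @export
buildSpherePhantom <- function(spec) {
  stopifnot(inherits(spec, "spherePhantomSpec"))
  dx <- spec$voxelSizeCm
  gd <- spec$gridDim
  bodyR <- spec$bodyDiameterCm / 2
  diams <- sort(spec$sphereDiametersMm, decreasing = TRUE)
  n <- length(diams)
  ringR <- spec$ringRadiusFraction * bodyR
  ang <- (spec$ringStartAngleDeg + (seq_len(n) - 1) * 360 / n) * pi / 180
  centres <- cbind(ringR * cos(ang), ringR * sin(ang), 0)
  radii <- diams / 20          # mm diameter -> cm radius
  .checkInsertLayout(centres, radii, bodyR, "sphere")
  bodyFrac <- .cylinderFrac(gd, dx, c(0, 0), bodyR, spec$supersample)
  sphereFrac <- array(0, gd)
  shellFrac <- array(0, gd)
  for (i in seq_len(n)) {
    inner <- .sphereFrac(gd, dx, centres[i, ], radii[i], spec$supersample)
    outer <- .sphereFrac(gd, dx, centres[i, ],
      radii[i] + .SHELL_THICKNESS_CM, spec$supersample)
    sphereFrac <- sphereFrac + inner
    shellFrac <- shellFrac + (outer - inner)
  }
  sphereFrac[sphereFrac > 1] <- 1
  shellFrac[shellFrac > 1] <- 1
  activity <- spec$backgroundActivity * bodyFrac +
    (spec$sphereActivity - spec$backgroundActivity) * sphereFrac
  mu <- MU_WATER_140KEV * bodyFrac
  ## CT shows water everywhere in the body; only the glass shells stand out
  anat <- .HU_AIR * (1 - bodyFrac) + .HU_SHELL * shellFrac
  list(activity = spectVolume(activity, dx),
    mu = spectVolume(mu, dx),
    anatomical = spectVolume(anat, dx),
    geometry = data.frame(id = seq_len(n), x = centres[, 1],
      y = centres[, 2], z = centres[, 3], diameterMm = diams))
}

#' Build the rod phantom volumes
#'
#' @param spec a [rodPhantomSpec()].
#' @return As [buildSpherePhantom()]: \code{activity}, \code{mu},
#'   \code{anatomical} volumes and the rod \code{geometry} data.frame.
#' @export
buildRodPhantom <- function(spec) {
  stopifnot(inherits(spec, "rodPhantomSpec"))
  dx <- spec$voxelSizeCm
  gd <- spec$gridDim
  tankR <- spec$tankDiameterCm / 2
  diams <- switch(spec$mode,
    hot = sort(spec$hotRodDiametersMm, decreasing = TRUE),
    cold = sort(spec$coldRodDiametersMm, decreasing = TRUE),
    uniform = numeric(0))
  n <- length(diams)
  tankFrac <- .cylinderFrac(gd, dx, c(0, 0), tankR, spec$supersample)
  rodFrac <- array(0, gd)
  geometry <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
    z = numeric(0), diameterMm = numeric(0))
  if (n > 0) {
    ringR <- spec$ringRadiusFraction * tankR
    ang <- (90 + (seq_len(n) - 1) * 360 / n) * pi / 180
    centres <- cbind(ringR * cos(ang), ringR * sin(ang), 0)
    radii <- diams / 20
    .checkInsertLayout(centres, radii, tankR, "rod")
    for (i in seq_len(n))
      rodFrac <- rodFrac +
        .cylinderFrac(gd, dx, centres[i, 1:2], radii[i], spec$supersample)
    rodFrac[rodFrac > 1] <- 1
    geometry <- data.frame(id = seq_len(n), x = centres[, 1],
      y = centres[, 2], z = 0, diameterMm = diams)
  }
  activity <- switch(spec$mode,
    hot = spec$rodActivity * rodFrac,
    cold = spec$backgroundActivity * (tankFrac - rodFrac),
    uniform = spec$backgroundActivity * tankFrac)
  activity[activity < 0] <- 0
  mu <- MU_WATER_140KEV * tankFrac
  anat <- .HU_AIR * (1 - tankFrac) + .HU_ROD * rodFrac
  list(activity = spectVolume(activity, dx),
    mu = spectVolume(mu, dx),
    anatomical = spectVolume(anat, dx),
    geometry = geometry)
}

#' Simulate a Poisson SPECT acquisition of a phantom
#'
#' Forward projects the activity through the full system model, scales
#' the noiseless projections to the requested expected total counts, and
#' draws independent Poisson counts per bin with a fixed seed (recorded
#' in the output metadata; the same seed reproduces the output exactly).
#' The caller's random-number state is left untouched.
#'
#' @param activity activity [SpectVolume-class].
#' @param mu attenuation [SpectVolume-class] or NULL.
#' @param geometry an [AcquisitionGeometry-class].
#' @param collimator a [CollimatorModel-class].
#' @param totalCounts expected total detected counts (> 0).
#' @param seed integer random seed.
#' @param model optional precomputed [systemModel()].
#' @return A [ProjectionSet-class] of counts; metadata records
#'   \code{seed}, \code{totalCounts} and the applied \code{scale}.
#' @export
simulateAcquisition <- function(activity, mu, geometry, collimator,
    totalCounts, seed = 1L, model = NULL) {
  if (!is.finite(totalCounts) || totalCounts <= 0)
    stop("totalCounts must be > 0", call. = FALSE)
  noiseless <- forwardProject(activity, geometry, collimator, mu,
    model = model)
  s <- sum(noiseless@data)
  if (s <= 0) stop("activity projects to zero counts", call. = FALSE)
  scale <- totalCounts / s
  lam <- noiseless@data * scale
  oldSeed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(oldSeed)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", oldSeed, envir = globalenv())
  })
  set.seed(seed)
  counts <- array(rpois(length(lam), lam), dim(lam))
  projectionSet(counts, noiseless@geometry,
    metadata = list(seed = as.integer(seed), totalCounts = totalCounts,
      scale = scale))
}
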