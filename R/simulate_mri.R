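# Continuous synthetic "scene" shared by all simulated modalities, defined
# in the optoacoustic reference frame (mm). Vessels come from the phantom's
# vessel-labelled absorbers; the brain background is a smooth super-Gaussian
# blob with a few fixed internal structures so that intensity-based
# registration has features to lock onto.
.sceneVessels <- function(phantom, pts) {
  ab <- phantom@absorbers
  out <- numeric(nrow(pts))
  for (k in which(ab$compartment == "vessel")) {
    sig <- max(ab$radiusMm[k], 0.2)
    d2 <- (pts[, 1] - ab$x[k])^2 + (pts[, 2] - ab$y[k])^2 +
      (pts[, 3] - ab$z[k])^2
    out <- out + exp(-d2 / (2 * sig^2))
  }
  out
}

.sceneBrain <- function(pts) {
  r2 <- (pts[, 1] / 4.5)^2 + (pts[, 2] / 3.5)^2 + ((pts[, 3] - 0.5) / 2.5)^2
  base <- exp(-r2^2)
  feats <- rbind(c(1.5, 0.8, 0.6, 0.8), c(-1.2, -1.0, 1.0, 0.6),
                 c(0.4, -1.6, 0.2, 0.5), c(-2.0, 1.8, -0.5, 0.7))
  for (k in seq_len(nrow(feats))) {
    d2 <- (pts[, 1] - feats[k, 1])^2 + (pts[, 2] - feats[k, 2])^2 +
      (pts[, 3] - feats[k, 3])^2
    base <- base + 0.4 * exp(-d2 / (2 * feats[k, 4]^2))
  }
  base
}

#' Default MRI sequence grids
#'
#' Voxel grids matching the acquisition matrices of the emulated
#' sequences: MRA 256 x 256 x 20 (78 um in-plane, 0.3 mm slices),
#' T1-transverse 128 x 128 x 20, T1-coronal 160 x 80 x 11 (0.7 mm
#' slices), BOLD EPI 80 x 40 x 11 (250 um in-plane, 0.7 mm slices).
#'
#' @return named list of [VoxelGrid-class] objects.
#' @export
defaultMriGrids <- function() {
  list(
    mra = voxelGrid(c(-10, -10, -3), c(20 / 256, 20 / 256, 0.3),
                    c(256L, 256L, 20L)),
    t1Transverse = voxelGrid(c(-10, -10, -3), c(20 / 128, 20 / 128, 0.3),
                             c(128L, 128L, 20L)),
    t1Coronal = voxelGrid(c(-10, -5, -3.85), c(0.125, 0.125, 0.7),
                          c(160L, 80L, 11L)),
    bold = voxelGrid(c(-10, -5, -3.85), c(0.25, 0.25, 0.7),
                     c(80L, 40L, 11L))
  )
}

#' Simulate rigidly offset MRI volumes of the phantom scene
#'
#' Renders MRA (vessel-hyperintense), two T1-weighted anatomical volumes
#' (smooth brain-shaped background) and a 4-D BOLD series from the same
#' continuous scene as the optoacoustic phantom, each on its own grid and
#' under its own known rigid transform (volume frame to reference frame):
#' a volume's value at grid point x is scene(T(x)), so registering it to a
#' reference-frame rendering recovers T as ground truth. The BOLD series
#' is modulated by the paradigm with sign opposite to HbR (i.e. it rises
#' under hyperoxia), using the parenchyma compartment trace.
#'
#' @param phantom a [Phantom-class]; vessel-labelled absorbers become the
#'   MRA vessels.
#' @param grids named list of grids as in [defaultMriGrids()].
#' @param transforms named list of [RigidTransform-class] per volume
#'   (mra, t1Transverse, t1Coronal, bold); identity by default.
#' @param hemo hemodynamics data.frame from
#'   [simulateParadigmHemodynamics()] driving the BOLD modulation; when
#'   NULL a flat series of \code{nBoldVolumes} is produced.
#' @param boldGain fractional BOLD amplitude per unit saturation change.
#' @param noiseSd additive Gaussian noise (relative units).
#' @param seed integer seed.
#' @param nBoldVolumes BOLD repetitions when no hemodynamics are given.
#' @return list with mra, t1Transverse, t1Coronal ([ImageVolume-class]),
#'   bold ([VolumeSeries-class]), oatReference (vessel scene rendered on
#'   the reconstruction grid), and the ground-truth \code{transforms}.
#' @export
simulateMriVolumes <- function(phantom, grids = defaultMriGrids(),
                               transforms = list(), hemo = NULL,
                               boldGain = 0.6, noiseSd = 0.005,
                               seed = NULL, nBoldVolumes = 10L) {
  need <- c("mra", "t1Transverse", "t1Coronal", "bold")
  if (!all(need %in% names(grids)))
    stop("grids must name ", paste(need, collapse = ", "))
  for (nm in need)
    if (is.null(transforms[[nm]])) transforms[[nm]] <- rigidTransform()
  if (!is.null(seed)) set.seed(seed)
  render <- function(grid, transform, fun) {
    pts <- transformPoints(transform, voxelCenters(grid))
    vals <- fun(pts)
    if (noiseSd > 0) vals <- vals + stats::rnorm(length(vals), sd = noiseSd)
    new("ImageVolume", grid = grid, values = array(vals, grid@dim))
  }
  mra <- render(grids$mra, transforms$mra,
                function(p) .sceneVessels(phantom, p) + 0.1 * .sceneBrain(p))
  t1fun <- function(p) .sceneBrain(p) + 0.05 * .sceneVessels(phantom, p)
  t1t <- render(grids$t1Transverse, transforms$t1Transverse, t1fun)
  t1c <- render(grids$t1Coronal, transforms$t1Coronal, t1fun)
  # BOLD: base brain signal modulated opposite in sign to HbR
  pts <- transformPoints(transforms$bold, voxelCenters(grids$bold))
  base <- .sceneBrain(pts)
  if (!is.null(hemo)) {
    tr <- hemo[hemo$compartment == "parenchyma", ]
    if (!nrow(tr)) tr <- hemo[hemo$compartment == hemo$compartment[1], ]
    resp <- boldGain * (tr$so2 - tr$so2[1])  # -dHbR/HbT up to scale
    times <- tr$timeS
  } else {
    resp <- numeric(nBoldVolumes)
    times <- seq_len(nBoldVolumes) - 1
  }
  nT <- length(resp)
  boldArr <- array(0, c(grids$bold@dim, nT))
  for (k in seq_len(nT)) {
    v <- base * (1 + resp[k])
    if (noiseSd > 0) v <- v + stats::rnorm(length(v), sd = noiseSd)
    boldArr[, , , k] <- v
  }
  bold <- new("VolumeSeries", grid = grids$bold, values = boldArr,
              timeS = times)
  oatGrid <- voxelGrid()
  oatRef <- new("ImageVolume", grid = oatGrid,
                values = array(.sceneVessels(phantom,
                                             voxelCenters(oatGrid)),
                               oatGrid@dim))
  list(mra = mra, t1Transverse = t1t, t1Coronal = t1c, bold = bold,
       oatReference = oatRef, transforms = transforms)
}

#' Intensity-weighted centroid of a volume
#'
#' Centroid (mm, in the volume's own frame) of voxels above a threshold
#' fraction of the maximum; the standard oracle for vessel-landmark
#' positions in registration checks.
#'
#' @param volume an [ImageVolume-class].
#' @param thresholdFraction fraction of the maximum (default 0.5).
#' @return length-3 numeric (mm).
#' @export
intensityCentroid <- function(volume, thresholdFraction = 0.5) {
  v <- volume@values
  v[is.na(v)] <- 0
  thr <- thresholdFraction * max(v)
  w <- ifelse(v >= thr, v, 0)
  pts <- voxelCenters(volume@grid)
  colSums(pts * as.numeric(w)) / sum(w)
}
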