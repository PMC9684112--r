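# Shared fixtures, all generated in code at test time.

# Small detection array: quasi-uniform cap layout with few channels and a
# short record, keeping streams light while preserving the geometry
# invariants.
smallGeometry <- function(nChannels = 8L, nSamples = 128L) {
  arrayGeometry(buildHemisphericalArray(nChannels)@positions,
                nSamples = nSamples)
}

# Static single-vessel phantom with absorption tabulated at the five
# excitation wavelengths.
smallPhantom <- function() {
  phantom(data.frame(x = 0.5, y = 0, z = 0.3, radiusMm = 0.1,
                     compartment = "vessel"),
          absorption = matrix(c(1, 2, 3, 4, 5), 1, 5))
}

# Short interleaved stream (60 s, 50 Hz) used by QC and restoration tests.
smallStream <- function(durationS = 60, noiseSd = 0.01, seed = 2,
                        geometry = smallGeometry()) {
  simulateStream(smallPhantom(), geometry,
                 acquisitionTiming(durationS = durationS),
                 noiseSd = noiseSd, seed = seed)
}

# Smooth feature-rich volume for registration tests: the brain-shaped
# scene rendered on a grid, optionally under a rigid transform (volume
# value at x = scene(T x)), so T is the ground-truth volume-to-reference
# transform.
featureVolume <- function(grid, transform = rigidTransform()) {
  pts <- transformPoints(transform, voxelCenters(grid))
  new("ImageVolume", grid = grid,
      values = array(oatpipe:::.sceneBrain(pts), grid@dim))
}

registrationGrid <- function(dim = c(40L, 40L, 20L), voxel = 0.3) {
  voxelGrid(-dim * voxel / 2, voxel, dim)
}

# Maximum absolute elementwise difference between the 4x4 matrices of two
# rigid transforms (insensitive to the centre parameterisation).
transformMatrixError <- function(a, b) {
  max(abs(transformMatrix(a) - transformMatrix(b)))
}

# Position (mm) of the absolute intensity peak of a volume.
peakPosition <- function(vol) {
  pk <- arrayInd(which.max(abs(vol@values)), dim(vol@values))
  as.numeric(vol@grid@originMm + (pk - 0.5) * vol@grid@voxelSizeMm)
}

# Cache for fixtures shared between expensive acceptance checks.
.fixtureCache <- new.env(parent = emptyenv())

cachedFixture <- function(name, expr) {
  if (!exists(name, envir = .fixtureCache))
    assign(name, force(expr), envir = .fixtureCache)
  get(name, envir = .fixtureCache)
}
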