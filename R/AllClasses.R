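#' @import methods
NULL

setClassUnion("logicalOrNULL", c("logical", "NULL"))

#' Hemispherical detection array geometry
#'
#' Describes the ultrasound detection array used for volumetric optoacoustic
#' tomography: element positions on a spherical cap, together with the
#' sampling constants of the data acquisition chain. All coordinates are in
#' mm, with the origin at the centre of the detection sphere and the z axis
#' along the array symmetry axis pointing into the tissue.
#'
#' @slot positions numeric matrix, n x 3, element centres in mm.
#' @slot radiusMm sphere radius in mm.
#' @slot apertureDeg full angular aperture of the cap in degrees.
#' @slot samplingRate samples per second of the DAQ.
#' @slot nSamples number of temporal samples per recorded frame.
#' @slot centerFrequencyHz transducer centre frequency in Hz.
#' @slot bandpassHz length-2 numeric, detection band low/high cut in Hz.
#' @slot delayS acquisition pre-trigger delay in seconds: the first recorded
#'   sample corresponds to time \code{delayS} after the laser pulse.
#'
#' @seealso [buildHemisphericalArray()]
#' @export
setClass("ArrayGeometry",
  slots = c(
    positions = "matrix",
    radiusMm = "numeric",
    apertureDeg = "numeric",
    samplingRate = "numeric",
    nSamples = "integer",
    centerFrequencyHz = "numeric",
    bandpassHz = "numeric",
    delayS = "numeric"
  )
)

setValidity("ArrayGeometry", function(object) {
  msg <- character()
  p <- object@positions
  if (ncol(p) != 3L) msg <- c(msg, "positions must be an n x 3 matrix")
  if (object@radiusMm <= 0) msg <- c(msg, "radiusMm must be positive")
  if (object@samplingRate <= 0) msg <- c(msg, "samplingRate must be positive")
  if (object@apertureDeg <= 0 || object@apertureDeg > 180)
    msg <- c(msg, "apertureDeg must lie in (0, 180]")
  if (object@nSamples < 1L) msg <- c(msg, "nSamples must be >= 1")
  if (length(object@bandpassHz) != 2L || any(object@bandpassHz <= 0) ||
      diff(object@bandpassHz) <= 0)
    msg <- c(msg, "bandpassHz must be an increasing positive pair")
  if (ncol(p) == 3L && nrow(p) > 0L) {
    r <- sqrt(rowSums(p^2))
    if (any(abs(r - object@radiusMm) > 1e-4))
      msg <- c(msg, "all elements must lie on the sphere (within 0.1 um)")
    # polar angle measured from the -z pole (detector side of the bowl)
    theta <- acos(pmin(1, pmax(-1, -p[, 3] / r))) * 180 / pi
    if (any(theta > object@apertureDeg / 2 + 1e-6))
      msg <- c(msg, "element polar angle exceeds half the angular aperture")
  }
  if (length(msg)) msg else TRUE
})

#' Acquisition timing of the interleaved multi-wavelength scan
#'
#' @slot prfHz laser pulse repetition frequency (Hz).
#' @slot wavelengthsNm excitation wavelengths swept on a per-pulse basis (nm).
#' @slot boldTrS repetition time of the concurrent BOLD EPI sequence (s).
#' @slot boldSlices number of slices excited within one BOLD TR.
#' @slot durationS total acquisition duration (s).
#' @export
setClass("AcquisitionTiming",
  slots = c(
    prfHz = "numeric",
    wavelengthsNm = "numeric",
    boldTrS = "numeric",
    boldSlices = "integer",
    durationS = "numeric"
  )
)

setValidity("AcquisitionTiming", function(object) {
  msg <- character()
  if (object@prfHz <= 0) msg <- c(msg, "prfHz must be positive")
  if (length(object@wavelengthsNm) < 1L || any(object@wavelengthsNm <= 0))
    msg <- c(msg, "wavelengthsNm must be positive")
  if (object@boldTrS <= 0) msg <- c(msg, "boldTrS must be positive")
  if (object@boldSlices < 1L) msg <- c(msg, "boldSlices must be >= 1")
  if (object@durationS <= 0) msg <- c(msg, "durationS must be positive")
  if (length(msg)) msg else TRUE
})

#' Optical absorption phantom
#'
#' A collection of spherical absorbers with per-wavelength absorption
#' coefficients, each tagged as belonging to the vessel or parenchyma
#' compartment, over a (possibly wavelength-dependent) background.
#'
#' @slot absorbers data.frame with columns x, y, z (mm), radiusMm and
#'   compartment ("vessel" or "parenchyma").
#' @slot absorption numeric matrix, absorbers x wavelengths, absorption
#'   coefficients (relative units).
#' @slot background numeric, background absorption per wavelength.
#' @slot wavelengthsNm wavelengths at which absorption is tabulated.
#' @export
setClass("Phantom",
  slots = c(
    absorbers = "data.frame",
    absorption = "matrix",
    background = "numeric",
    wavelengthsNm = "numeric"
  )
)

setValidity("Phantom", function(object) {
  msg <- character()
  ab <- object@absorbers
  need <- c("x", "y", "z", "radiusMm", "compartment")
  if (!all(need %in% names(ab)))
    msg <- c(msg, "absorbers must have columns x, y, z, radiusMm, compartment")
  else {
    if (nrow(ab) > 0 && any(ab$radiusMm <= 0))
      msg <- c(msg, "absorber radii must be positive")
    if (nrow(ab) > 0 && !all(ab$compartment %in% c("vessel", "parenchyma")))
      msg <- c(msg, "compartment must be 'vessel' or 'parenchyma'")
  }
  if (nrow(object@absorption) != nrow(ab))
    msg <- c(msg, "absorption must have one row per absorber")
  if (nrow(ab) > 0 && ncol(object@absorption) != length(object@wavelengthsNm))
    msg <- c(msg, "absorption must have one column per wavelength")
  if (any(object@absorption < 0)) msg <- c(msg, "absorption must be >= 0")
  if (length(object@background) != length(object@wavelengthsNm))
    msg <- c(msg, "background must have one value per wavelength")
  if (length(msg)) msg else TRUE
})

#' Breathing-gas challenge paradigm
#'
#' A baseline period on the carbogen-enriched baseline mixture followed by
#' repeated normoxia/hyperoxia cycles.
#'
#' @slot baselineDurationS baseline duration (s).
#' @slot nCycles number of stimulation cycles.
#' @slot normoxiaDurationS normoxia segment per cycle (s).
#' @slot hyperoxiaDurationS hyperoxia segment per cycle (s).
#' @slot fio2Baseline inspired O2 fraction at baseline.
#' @slot fio2Normoxia inspired O2 fraction during normoxia.
#' @slot fio2Hyperoxia inspired O2 fraction during hyperoxia.
#' @slot airO2Fraction O2 fraction of medical air.
#' @export
setClass("StimulusParadigm",
  slots = c(
    baselineDurationS = "numeric",
    nCycles = "integer",
    normoxiaDurationS = "numeric",
    hyperoxiaDurationS = "numeric",
    fio2Baseline = "numeric",
    fio2Normoxia = "numeric",
    fio2Hyperoxia = "numeric",
    airO2Fraction = "numeric"
  )
)

setValidity("StimulusParadigm", function(object) {
  msg <- character()
  dur <- c(object@baselineDurationS, object@normoxiaDurationS,
           object@hyperoxiaDurationS)
  if (any(dur <= 0)) msg <- c(msg, "durations must be positive")
  if (object@nCycles < 1L) msg <- c(msg, "nCycles must be >= 1")
  f <- c(object@fio2Baseline, object@fio2Normoxia, object@fio2Hyperoxia,
         object@airO2Fraction)
  if (any(f <= 0) || any(f > 1)) msg <- c(msg, "FiO2 fractions must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Single-shot sinogram
#'
#' One laser shot's channel-by-sample pressure matrix with its acquisition
#' tags.
#'
#' @slot data numeric matrix, channels x samples.
#' @slot wavelengthNm excitation wavelength (nm).
#' @slot timestampS shot time relative to acquisition start (s).
#' @slot pulseEnergyMj laser pulse energy (mJ).
#' @slot frameIndex position of the frame in its stream.
#' @export
setClass("SinogramFrame",
  slots = c(
    data = "matrix",
    wavelengthNm = "numeric",
    timestampS = "numeric",
    pulseEnergyMj = "numeric",
    frameIndex = "integer"
  )
)

setValidity("SinogramFrame", function(object) {
  if (!all(is.finite(object@data))) return("sinogram entries must be finite")
  TRUE
})

#' Time-ordered interleaved sinogram stream
#'
#' @slot data numeric array, channels x samples x frames.
#' @slot wavelengthNm per-frame excitation wavelength (nm).
#' @slot timestampS per-frame shot time (s).
#' @slot pulseEnergyMj per-frame pulse energy (mJ).
#' @slot geometry the [ArrayGeometry-class] the frames were recorded with.
#' @slot prfHz pulse repetition frequency of the stream (Hz).
#' @slot corruptMask optional ground-truth/detected corruption flags.
#' @export
setClass("SinogramStream",
  slots = c(
    data = "array",
    wavelengthNm = "numeric",
    timestampS = "numeric",
    pulseEnergyMj = "numeric",
    geometry = "ArrayGeometry",
    prfHz = "numeric",
    corruptMask = "logicalOrNULL"
  )
)

setValidity("SinogramStream", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L) msg <- c(msg, "data must be channels x samples x frames")
  else {
    n <- d[3]
    if (length(object@wavelengthNm) != n)
      msg <- c(msg, "wavelengthNm must have one entry per frame")
    if (length(object@timestampS) != n)
      msg <- c(msg, "timestampS must have one entry per frame")
    if (length(object@pulseEnergyMj) != n)
      msg <- c(msg, "pulseEnergyMj must have one entry per frame")
    if (!is.null(object@corruptMask) && length(object@corruptMask) != n)
      msg <- c(msg, "corruptMask must have one entry per frame")
    if (n > 1 && any(diff(object@timestampS) < 0))
      msg <- c(msg, "timestamps must be non-decreasing")
  }
  if (length(msg)) msg else TRUE
})

#' Two-region speed-of-sound model
#'
#' Speed of sound of the acoustic coupling medium (heavy water) and of the
#' tissue, separated by a single-valued parametric interface surface
#' z = s(x, y). The water occupies the detector side (z below the surface),
#' the tissue the far side. An empty interface, or equal speeds, gives the
#' uniform model.
#'
#' @slot cWater speed of sound in the coupling water (m/s).
#' @slot cTissue speed of sound in tissue (m/s).
#' @slot interface empty list for a uniform medium, else a list with
#'   polynomial surface coefficients z0, gx, gy and optionally qxx, qyy, qxy
#'   so that s(x, y) = z0 + gx x + gy y + qxx x^2 + qyy y^2 + qxy x y (mm).
#' @export
setClass("TwoRegionSOSModel",
  slots = c(cWater = "numeric", cTissue = "numeric", interface = "list")
)

setValidity("TwoRegionSOSModel", function(object) {
  msg <- character()
  if (object@cWater <= 0 || object@cTissue <= 0)
    msg <- c(msg, "speeds of sound must be positive")
  if (length(object@interface) &&
      !all(c("z0", "gx", "gy") %in% names(object@interface)))
    msg <- c(msg, "interface needs at least coefficients z0, gx, gy")
  if (length(msg)) msg else TRUE
})

#' Voxel grid with physical coordinates
#'
#' Voxel indices map to mm via origin + (index - 1 + 0.5) * voxelSize
#' (voxel-centre convention).
#'
#' @slot originMm corner of the grid (mm), length 3.
#' @slot voxelSizeMm voxel edge lengths (mm), length 3.
#' @slot dim integer grid dimensions, length 3.
#' @export
setClass("VoxelGrid",
  slots = c(originMm = "numeric", voxelSizeMm = "numeric", dim = "integer")
)

setValidity("VoxelGrid", function(object) {
  msg <- character()
  if (length(object@originMm) != 3L) msg <- c(msg, "originMm must have length 3")
  if (length(object@voxelSizeMm) != 3L || any(object@voxelSizeMm <= 0))
    msg <- c(msg, "voxelSizeMm must be 3 positive values")
  if (length(object@dim) != 3L || any(object@dim < 1L))
    msg <- c(msg, "dim must be 3 positive integers")
  if (length(msg)) msg else TRUE
})

#' A scalar image volume on a voxel grid
#'
#' @slot grid the [VoxelGrid-class].
#' @slot values numeric 3-D array matching \code{dim(grid)}.
#' @export
setClass("ImageVolume", slots = c(grid = "VoxelGrid", values = "array"))

setValidity("ImageVolume", function(object) {
  if (!identical(dim(object@values), as.integer(object@grid@dim)))
    return("values dimensions must match the grid")
  TRUE
})

#' Reconstructed optoacoustic volume
#'
#' @slot wavelengthNm excitation wavelength of the reconstruction (nm).
#' @slot timestampS acquisition time of the underlying sinogram (s).
#' @export
setClass("ReconVolume", contains = "ImageVolume",
  slots = c(wavelengthNm = "numeric", timestampS = "numeric")
)

#' A 4-D volume series (e.g. BOLD) on a fixed grid
#'
#' @slot grid the [VoxelGrid-class].
#' @slot values numeric 4-D array, space x time.
#' @slot timeS time axis (s).
#' @export
setClass("VolumeSeries",
  slots = c(grid = "VoxelGrid", values = "array", timeS = "numeric")
)

setValidity("VolumeSeries", function(object) {
  d <- dim(object@values)
  if (length(d) != 4L) return("values must be a 4-D array")
  if (!identical(d[1:3], as.integer(object@grid@dim)))
    return("spatial dimensions must match the grid")
  if (d[4] != length(object@timeS)) return("time axis length mismatch")
  TRUE
})

#' Per-voxel hemodynamic component series
#'
#' Voxel-wise HbO, HbR, HbT and sO2 at the analysis rate (1 Hz). HbT is
#' identically HbO + HbR; sO2 is NA-masked wherever HbT is at or below the
#' configured floor.
#'
#' @slot grid the reconstruction [VoxelGrid-class].
#' @slot hbo,hbr,hbt,so2 4-D arrays, space x time.
#' @slot timeS time axis (s).
#' @export
setClass("HemoSeries",
  slots = c(grid = "VoxelGrid", hbo = "array", hbr = "array",
            hbt = "array", so2 = "array", timeS = "numeric")
)

setValidity("HemoSeries", function(object) {
  d <- dim(object@hbo)
  for (s in c("hbr", "hbt", "so2"))
    if (!identical(dim(slot(object, s)), d))
      return("component arrays must share dimensions")
  if (d[length(d)] != length(object@timeS)) return("time axis length mismatch")
  TRUE
})

#' Six-degree-of-freedom rigid transform
#'
#' Rotation is parameterised as intrinsic z-y-x Euler angles applied about
#' \code{centerMm}, followed by the translation: a point p maps to
#' R (p - center) + center + t.
#'
#' @slot anglesDeg rotations about z, y, x in degrees (applied in that order).
#' @slot translationMm translation in mm.
#' @slot centerMm centre of rotation in mm.
#' @export
setClass("RigidTransform",
  slots = c(anglesDeg = "numeric", translationMm = "numeric",
            centerMm = "numeric")
)

setValidity("RigidTransform", function(object) {
  if (length(object@anglesDeg) != 3L || length(object@translationMm) != 3L ||
      length(object@centerMm) != 3L)
    return("anglesDeg, translationMm and centerMm must each have length 3")
  TRUE
})

#' Sinogram corruption report
#'
#' Output of the residual-based corruption detector, optionally augmented
#' with the per-second intensity map and the corruption power spectrum.
#'
#' @slot mask per-frame corruption flag.
#' @slot residualL1 per-frame L1 norm of the residual after subtracting the
#'   nominal per-channel values.
#' @slot threshold detection threshold(s), named by wavelength.
#' @slot wavelengthNm per-frame wavelength tags.
#' @slot timestampS per-frame timestamps (s).
#' @slot intensityMap data.frame (timeS, count): corrupted frames per bin.
#' @slot spectrum data.frame (frequencyHz, power).
#' @slot peakFrequencyHz non-DC spectral peak (Hz); NA if undefined.
#' @export
setClass("CorruptionReport",
  slots = c(
    mask = "logical",
    residualL1 = "numeric",
    threshold = "numeric",
    wavelengthNm = "numeric",
    timestampS = "numeric",
    intensityMap = "data.frame",
    spectrum = "data.frame",
    peakFrequencyHz = "numeric"
  )
)

setValidity("CorruptionReport", function(object) {
  n <- length(object@mask)
  if (length(object@residualL1) != n || length(object@wavelengthNm) != n ||
      length(object@timestampS) != n)
    return("per-frame slots must share the mask length")
  if (any(object@residualL1 < 0)) return("residuals must be non-negative")
  TRUE
})
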