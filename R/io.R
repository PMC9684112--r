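#' Write / read a sinogram stream
#'
#' Streams are serialized to R's native RDS format: a tagged list holding
#' the data array, per-frame metadata, the array geometry and the frame
#' rate. Round-trips are bit-exact.
#'
#' @param stream a [SinogramStream-class].
#' @param path file path (conventionally .rds).
#' @return \code{writeSinogramStream} returns the path invisibly;
#'   \code{readSinogramStream} returns the [SinogramStream-class].
#' @export
writeSinogramStream <- function(stream, path) {
  obj <- list(format = "oatpipe-sinogram-stream", version = 1L,
              data = stream@data, wavelengthNm = stream@wavelengthNm,
              timestampS = stream@timestampS,
              pulseEnergyMj = stream@pulseEnergyMj,
              prfHz = stream@prfHz, corruptMask = stream@corruptMask,
              geometry = list(positions = stream@geometry@positions,
                              radiusMm = stream@geometry@radiusMm,
                              apertureDeg = stream@geometry@apertureDeg,
                              samplingRate = stream@geometry@samplingRate,
                              nSamples = stream@geometry@nSamples,
                              centerFrequencyHz =
                                stream@geometry@centerFrequencyHz,
                              bandpassHz = stream@geometry@bandpassHz,
                              delayS = stream@geometry@delayS))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname writeSinogramStream
#' @param path file path.
#' @export
readSinogramStream <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "oatpipe-sinogram-stream"))
    stop("not a sinogram stream file: missing format tag in ", path)
  for (f in c("data", "wavelengthNm", "timestampS", "geometry"))
    if (is.null(obj[[f]])) stop("stream file lacks field '", f, "'")
  g <- obj$geometry
  geom <- arrayGeometry(g$positions, g$radiusMm, g$apertureDeg,
                        g$samplingRate, g$nSamples, g$centerFrequencyHz,
                        g$bandpassHz, g$delayS)
  new("SinogramStream", data = obj$data, wavelengthNm = obj$wavelengthNm,
      timestampS = obj$timestampS, pulseEnergyMj = obj$pulseEnergyMj,
      geometry = geom, prfHz = obj$prfHz, corruptMask = obj$corruptMask)
}

# Affine of a VoxelGrid: maps 0-based voxel indices to the mm position of
# the voxel centre (NIfTI convention).
.gridAffine <- function(grid) {
  m <- diag(4)
  diag(m)[1:3] <- grid@voxelSizeMm
  m[1:3, 4] <- grid@originMm + 0.5 * grid@voxelSizeMm
  m
}

.gridFromAffine <- function(m, dim) {
  voxel <- sqrt(colSums(m[1:3, 1:3]^2))
  origin <- m[1:3, 4] - 0.5 * voxel
  voxelGrid(origin, voxel, dim[1:3])
}

#' Write / read volumes as NIfTI-1
#'
#' The grid is encoded in the qform/sform affine (voxel-centre
#' convention); 4-D series carry the time axis in the fourth dimension.
#'
#' @param volume an [ImageVolume-class], [ReconVolume-class] or
#'   [VolumeSeries-class].
#' @param path file path (.nii or .nii.gz).
#' @return \code{writeVolume} returns the path invisibly;
#'   \code{readVolume} returns an [ImageVolume-class] (or
#'   [VolumeSeries-class] for 4-D data, with a unit time axis).
#' @export
writeVolume <- function(volume, path) {
  vals <- volume@values
  grid <- volume@grid
  img <- RNifti::asNifti(vals)
  nd <- length(dim(vals))
  dt <- if (nd == 4L && length(volume@timeS) > 1L)
    diff(volume@timeS[1:2]) else if (nd == 4L) 1 else NULL
  RNifti::pixdim(img) <- c(grid@voxelSizeMm, dt)
  aff <- structure(.gridAffine(grid), code = 2L)
  img <- RNifti::`qform<-`(img, aff)
  img <- RNifti::`sform<-`(img, aff)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  d <- dim(img)
  grid <- .gridFromAffine(aff, d)
  if (length(d) == 4L) {
    dt <- RNifti::pixdim(img)
    dt <- if (length(dt) >= 4L) dt[4] else 1
    new("VolumeSeries", grid = grid, values = array(as.numeric(img), d),
        timeS = (seq_len(d[4]) - 1) * dt)
  } else {
    new("ImageVolume", grid = grid, values = array(as.numeric(img), d))
  }
}

#' Write / read rigid transforms as JSON
#'
#' Stores angles, translation, rotation centre and the convention tag
#' ("intrinsic-zyx-about-center"), plus the 4 x 4 affine for
#' interoperability.
#'
#' @param transform a [RigidTransform-class].
#' @param path file path (.json).
#' @export
writeTransform <- function(transform, path) {
  obj <- list(convention = "intrinsic-zyx-about-center",
              anglesDeg = transform@anglesDeg,
              translationMm = transform@translationMm,
              centerMm = transform@centerMm,
              affine = transformMatrix(transform))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname writeTransform
#' @export
readTransform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigidTransform(obj$anglesDeg, obj$translationMm, obj$centerMm)
}

#' Read and validate a pipeline configuration
#'
#' YAML (or JSON) configuration with sections seed, array, timing,
#' phantom, paradigm, corruption, recon, analysis and stages; unknown
#' top-level keys are rejected before any stage runs.
#'
#' @param path YAML/JSON file path, or a pre-parsed list.
#' @return validated config list with defaults filled in.
#' @export
readPipelineConfig <- function(path) {
  cfg <- if (is.list(path)) path
  else if (grepl("[.]json$", path)) jsonlite::read_json(path,
                                                        simplifyVector = TRUE)
  else yaml::read_yaml(path)
  known <- c("seed", "array", "timing", "phantom", "paradigm",
             "corruption", "recon", "analysis", "stages", "out")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown config key(s): ", paste(extra, collapse = ", "))
  defaults <- list(
    seed = 1L,
    array = list(nElements = 64L, radiusMm = 40, apertureDeg = 130,
                 samplingRate = 40e6, nSamples = 128L),
    timing = list(prfHz = 50, wavelengthsNm = c(700, 730, 755, 800, 850),
                  boldTrS = 0.995, boldSlices = 11L, durationS = 10),
    phantom = list(vesselSo2 = 0.95, parenchymaSo2 = 0.70),
    paradigm = list(),
    corruption = list(burstAmplitude = 5, burstChannelFraction = 0.25,
                      jitterSd = 0),
    recon = list(sosMode = "single", cWater = 1400, cTissue = 1530,
                 voxelSizeMm = 0.25, fovMm = c(6, 6, 3), muEffMm = 0.6),
    analysis = list(roiEdgeMm = 0.4),
    stages = list(simulate = TRUE, qc = TRUE, restore = TRUE, recon = TRUE,
                  unmix = TRUE, coreg = FALSE, analyze = TRUE)
  )
  for (s in names(defaults)) {
    if (is.null(cfg[[s]])) cfg[[s]] <- defaults[[s]]
    else if (is.list(defaults[[s]]))
      for (k in names(defaults[[s]]))
        if (is.null(cfg[[s]][[k]])) cfg[[s]][[k]] <- defaults[[s]][[k]]
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

# Provenance sidecar written next to every pipeline artifact.
.writeProvenance <- function(path, cfgPath, seed, stage, inputs = NULL) {
  obj <- list(stage = stage, seed = seed,
              configMd5 = if (!is.null(cfgPath) && file.exists(cfgPath))
                unname(tools::md5sum(cfgPath)) else NA,
              inputs = inputs,
              packageVersion =
                as.character(utils::packageVersion("oatpipe")),
              writtenAt = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(obj, paste0(path, ".prov.json"), auto_unbox = TRUE,
                       null = "null")
  invisible(NULL)
}
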