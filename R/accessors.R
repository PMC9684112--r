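#' Accessors for oatpipe data objects
#'
#' Small accessor family used instead of direct slot access: element
#' positions and sampling constants of an [ArrayGeometry-class], per-frame
#' metadata of a [SinogramStream-class], and values/grid of volumes.
#'
#' @param x the object.
#' @name accessors
NULL

#' @rdname accessors
setMethod("nChannels", "ArrayGeometry", function(x) nrow(x@positions))

#' @rdname accessors
setMethod("nChannels", "SinogramStream", function(x) dim(x@data)[1])

#' @rdname accessors
setMethod("nFrames", "SinogramStream", function(x) dim(x@data)[3])

#' @rdname accessors
setMethod("elementPositions", "ArrayGeometry", function(x) x@positions)

#' @rdname accessors
setMethod("samplingRate", "ArrayGeometry", function(x) x@samplingRate)

#' @rdname accessors
setMethod("wavelengths", "AcquisitionTiming", function(x) x@wavelengthsNm)

#' @rdname accessors
setMethod("wavelengths", "SinogramStream", function(x) x@wavelengthNm)

#' @rdname accessors
setMethod("timestamps", "SinogramStream", function(x) x@timestampS)

#' @rdname accessors
setMethod("sinogramData", "SinogramStream", function(x) x@data)

#' @rdname accessors
setMethod("sinogramData", "SinogramFrame", function(x) x@data)

#' @rdname accessors
setMethod("corruptMask", "SinogramStream", function(x) x@corruptMask)

#' @rdname accessors
setMethod("corruptMask", "CorruptionReport", function(x) x@mask)

#' @rdname accessors
setMethod("voxelValues", "ImageVolume", function(x) x@values)

#' @rdname accessors
setMethod("reconGrid", "ImageVolume", function(x) x@grid)

#' @rdname accessors
setMethod("reconGrid", "VolumeSeries", function(x) x@grid)

#' @rdname accessors
setMethod("reconGrid", "HemoSeries", function(x) x@grid)

#' @rdname totalDuration
#' @aliases totalDuration,StimulusParadigm-method
setMethod("totalDuration", "StimulusParadigm", function(x) {
  x@baselineDurationS +
    x@nCycles * (x@normoxiaDurationS + x@hyperoxiaDurationS)
})

#' @rdname totalDuration
setMethod("totalDuration", "AcquisitionTiming", function(x) x@durationS)

setMethod("show", "ArrayGeometry", function(object) {
  cat(sprintf(
    "ArrayGeometry: %d elements on a %.1f mm sphere (aperture %.0f deg)\n",
    nChannels(object), object@radiusMm, object@apertureDeg))
  cat(sprintf("  %g Msps, %d samples/frame, band %.1f-%.1f MHz, delay %.3f us\n",
    object@samplingRate / 1e6, object@nSamples,
    object@bandpassHz[1] / 1e6, object@bandpassHz[2] / 1e6,
    object@delayS * 1e6))
})

setMethod("show", "SinogramStream", function(object) {
  d <- dim(object@data)
  cat(sprintf("SinogramStream: %d frames of %d channels x %d samples\n",
              d[3], d[1], d[2]))
  cat(sprintf("  PRF %.1f Hz, wavelengths: %s nm, span %.2f s\n",
              object@prfHz,
              paste(sort(unique(object@wavelengthNm)), collapse = "/"),
              if (d[3]) diff(range(object@timestampS)) else 0))
  if (!is.null(object@corruptMask))
    cat(sprintf("  corruptMask present: %d flagged\n", sum(object@corruptMask)))
})

setMethod("show", "StimulusParadigm", function(object) {
  cat(sprintf(
    "StimulusParadigm: %.0f s baseline (FiO2 %.2f) + %d x [%.0f s normoxia (%.2f) / %.0f s hyperoxia (%.2f)] = %.0f s\n",
    object@baselineDurationS, object@fio2Baseline, object@nCycles,
    object@normoxiaDurationS, object@fio2Normoxia,
    object@hyperoxiaDurationS, object@fio2Hyperoxia, totalDuration(object)))
})

setMethod("show", "VoxelGrid", function(object) {
  cat(sprintf("VoxelGrid: %s voxels of %s mm, origin (%s) mm\n",
              paste(object@dim, collapse = " x "),
              paste(signif(object@voxelSizeMm, 3), collapse = " x "),
              paste(signif(object@originMm, 4), collapse = ", ")))
})

setMethod("show", "ImageVolume", function(object) {
  cat(sprintf("%s: %s, range [%.3g, %.3g]\n", class(object),
              paste(object@grid@dim, collapse = " x "),
              min(object@values), max(object@values)))
})

setMethod("show", "RigidTransform", function(object) {
  cat(sprintf(
    "RigidTransform: angles z/y/x = (%s) deg, translation (%s) mm, centre (%s) mm\n",
    paste(signif(object@anglesDeg, 4), collapse = ", "),
    paste(signif(object@translationMm, 4), collapse = ", "),
    paste(signif(object@centerMm, 4), collapse = ", ")))
})

setMethod("show", "CorruptionReport", function(object) {
  cat(sprintf("CorruptionReport: %d/%d frames flagged\n",
              sum(object@mask), length(object@mask)))
  if (length(object@threshold))
    cat("  thresholds:", paste(sprintf("%s nm: %.3g", names(object@threshold),
                                       object@threshold), collapse = "; "), "\n")
  if (length(object@peakFrequencyHz) && !is.na(object@peakFrequencyHz))
    cat(sprintf("  corruption spectrum peak: %.3f Hz\n",
                object@peakFrequencyHz))
})

setMethod("show", "HemoSeries", function(object) {
  d <- dim(object@hbo)
  cat(sprintf("HemoSeries: %s voxels, %d time points at %.2g s spacing\n",
              paste(d[1:3], collapse = " x "), d[4],
              if (d[4] > 1) diff(object@timeS[1:2]) else NA))
})
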