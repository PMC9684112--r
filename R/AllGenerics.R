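#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("elementPositions", function(x) standardGeneric("elementPositions"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname accessors
#' @export
setGeneric("timestamps", function(x) standardGeneric("timestamps"))

#' @rdname accessors
#' @export
setGeneric("sinogramData", function(x) standardGeneric("sinogramData"))

#' @rdname accessors
#' @export
setGeneric("corruptMask", function(x) standardGeneric("corruptMask"))

#' @rdname accessors
#' @export
setGeneric("voxelValues", function(x) standardGeneric("voxelValues"))

#' @rdname accessors
#' @export
setGeneric("reconGrid", function(x) standardGeneric("reconGrid"))

#' Total duration of a stimulation paradigm
#'
#' @param x a [StimulusParadigm-class] or [AcquisitionTiming-class].
#' @return duration in seconds.
#' @export
setGeneric("totalDuration", function(x) standardGeneric("totalDuration"))

#' Compose two rigid transforms
#'
#' \code{composeTransforms(t1, t2)} returns the transform applying
#' \code{t2} first and \code{t1} second (matrix product convention).
#'
#' @param t1,t2 [RigidTransform-class] objects.
#' @return a [RigidTransform-class].
#' @export
setGeneric("composeTransforms",
           function(t1, t2) standardGeneric("composeTransforms"))

#' Invert a rigid transform
#'
#' @param x a [RigidTransform-class].
#' @return the inverse [RigidTransform-class].
#' @export
setGeneric("invertTransform", function(x) standardGeneric("invertTransform"))
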