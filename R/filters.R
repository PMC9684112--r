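# Zero-phase Butterworth band-pass applied along the rows of a
# channels x samples matrix. Order refers to the single-pass design; the
# forward-backward application doubles the effective rolloff and removes
# phase distortion.
.bandpassRows <- function(mat, lowHz, highHz, fs, order = 4L) {
  nyq <- fs / 2
  if (!(lowHz > 0 && highHz > lowHz && highHz < nyq))
    stop("band must satisfy 0 < low < high < Nyquist (", nyq / 1e6, " MHz)")
  bf <- signal::butter(order, c(lowHz, highHz) / nyq, type = "pass")
  out <- mat
  for (i in seq_len(nrow(mat)))
    out[i, ] <- signal::filtfilt(bf, mat[i, ])
  out
}

#' Band-pass filter a sinogram
#'
#' Applies the detection band as a zero-phase Butterworth band-pass (order
#' 4, forward-backward) to every channel of a sinogram. The band-pass has
#' zero DC gain, so channel offsets are removed.
#'
#' @param x a [SinogramFrame-class], [SinogramStream-class], or a plain
#'   channels x samples matrix.
#' @param lowHz,highHz band edges in Hz (defaults 0.1 and 8 MHz).
#' @param samplingRate sampling rate in Hz; taken from the object's
#'   geometry when available.
#' @return object of the same type with filtered data.
#' @export
bandpassSinogram <- function(x, lowHz = 0.1e6, highHz = 8e6,
                             samplingRate = NULL) {
  if (is(x, "SinogramFrame")) {
    if (is.null(samplingRate)) samplingRate <- 40e6
    x@data <- .bandpassRows(x@data, lowHz, highHz, samplingRate)
    return(x)
  }
  if (is(x, "SinogramStream")) {
    fs <- if (is.null(samplingRate)) samplingRate(x@geometry) else samplingRate
    data <- x@data
    for (f in seq_len(dim(data)[3]))
      data[, , f] <- .bandpassRows(data[, , f], lowHz, highHz, fs)
    x@data <- data
    return(x)
  }
  if (is.null(samplingRate))
    stop("samplingRate is required for a plain matrix")
  .bandpassRows(as.matrix(x), lowHz, highHz, samplingRate)
}
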