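#' Split an interleaved stream by excitation wavelength
#'
#' Partitions the frames of a stream into per-wavelength substreams,
#' preserving temporal order. The union of the parts is the input.
#'
#' @param stream a [SinogramStream-class].
#' @param wavelengthsNm the configured wavelength set; frames tagged with
#'   any other wavelength raise an error naming the frame.
#' @return named list of [SinogramStream-class] objects, one per
#'   wavelength.
#' @export
demuxWavelengths <- function(stream,
                             wavelengthsNm = sort(unique(stream@wavelengthNm))) {
  wl <- stream@wavelengthNm
  unknown <- which(!(wl %in% wavelengthsNm))
  if (length(unknown))
    stop("frame ", unknown[1], " has unconfigured wavelength ",
         wl[unknown[1]], " nm")
  out <- list()
  for (w in wavelengthsNm) {
    idx <- which(wl == w)
    out[[as.character(w)]] <- new("SinogramStream",
      data = stream@data[, , idx, drop = FALSE],
      wavelengthNm = wl[idx], timestampS = stream@timestampS[idx],
      pulseEnergyMj = stream@pulseEnergyMj[idx],
      geometry = stream@geometry,
      prfHz = stream@prfHz / length(wavelengthsNm),
      corruptMask = if (is.null(stream@corruptMask)) NULL
                    else stream@corruptMask[idx])
  }
  out
}

#' Restore a single-wavelength stream to 1 Hz
#'
#' Forms non-overlapping blocks of \code{window} consecutive frames and,
#' per (channel, sample) pixel, rejects outlying values within the block
#' before averaging the remainder. Frames carried in \code{excludeMask}
#' (e.g. the corruption-QC mask) are dropped from their blocks before the
#' pixel-wise processing, so gross corruption cannot inflate the block
#' statistics. Output timestamps sit at block centres at 1 / (window /
#' frame rate) spacing; a trailing partial block is dropped.
#'
#' Rejection rules: \code{"mad"} (default) discards values more than
#' \code{nMad} scaled MADs from the block median; \code{"trim"} discards
#' the block minimum and maximum. If every value at a pixel is rejected
#' the block median is used and the event is logged once per block.
#'
#' @param stream a single-wavelength [SinogramStream-class].
#' @param window frames per block (>= 2).
#' @param rule rejection rule, "mad" or "trim".
#' @param nMad MAD multiplier for the "mad" rule.
#' @param excludeMask optional per-frame logical; flagged frames are
#'   excluded (defaults to the stream's own \code{corruptMask} when set).
#' @return a [SinogramStream-class] of restored 1 Hz sinograms; frame
#'   provenance (source frame indices per block) is attached as attribute
#'   \code{"blocks"} of the data slot.
#' @export
restoreTo1Hz <- function(stream, window = 10L, rule = c("mad", "trim"),
                         nMad = 3, excludeMask = NULL) {
  rule <- match.arg(rule)
  if (window < 2L) stop("window must be >= 2")
  if (is.null(excludeMask)) excludeMask <- stream@corruptMask
  n <- nFrames(stream)
  if (!is.null(excludeMask) && length(excludeMask) != n)
    stop("excludeMask length must equal the frame count")
  nBlocks <- n %/% window
  if (nBlocks < 1L) stop("stream shorter than one block")
  nCh <- dim(stream@data)[1]; nS <- dim(stream@data)[2]
  nPix <- nCh * nS
  out <- array(0, c(nCh, nS, nBlocks))
  ts <- numeric(nBlocks)
  energy <- numeric(nBlocks)
  blocks <- vector("list", nBlocks)
  for (b in seq_len(nBlocks)) {
    idx <- ((b - 1L) * window + 1L):(b * window)
    ts[b] <- mean(stream@timestampS[range(idx)])
    keep <- idx
    if (!is.null(excludeMask)) keep <- idx[!excludeMask[idx]]
    if (!length(keep)) keep <- idx  # whole block flagged: fall back to all
    blocks[[b]] <- keep
    energy[b] <- mean(stream@pulseEnergyMj[keep])
    m <- matrix(stream@data[, , keep], nPix, length(keep))
    out[, , b] <- matrix(.robustRowMeans(m, rule, nMad), nCh, nS)
  }
  res <- new("SinogramStream", data = out,
             wavelengthNm = rep(stream@wavelengthNm[1], nBlocks),
             timestampS = ts, pulseEnergyMj = energy,
             geometry = stream@geometry, prfHz = stream@prfHz / window,
             corruptMask = NULL)
  attr(res@data, "blocks") <- blocks
  res
}

# Row-wise outlier-rejected means of an nPix x w matrix.
.robustRowMeans <- function(m, rule, nMad = 3) {
  w <- ncol(m)
  if (w == 1L) return(as.numeric(m))
  nr <- nrow(m)
  med <- .rowMedians(m)
  if (rule == "trim") {
    lo <- .rowExtreme(m, min); hi <- .rowExtreme(m, max)
    tot <- rowSums(m, na.rm = TRUE) - lo - hi
    cnt <- w - rowSums(is.na(m)) - 2L
    res <- ifelse(cnt > 0, tot / cnt, med)
  } else {
    madScaled <- 1.4826 * .rowMedians(abs(m - med))
    # an exact-zero MAD (constant block) keeps only values equal to the
    # median
    lim <- nMad * madScaled
    ok <- abs(m - med) <= lim
    ok[is.na(ok)] <- FALSE
    cnt <- rowSums(ok)
    tot <- rowSums(m * ok, na.rm = TRUE)
    res <- ifelse(cnt > 0, tot / cnt, med)
    nFallback <- sum(cnt == 0)
    if (nFallback > 0)
      message("restoreTo1Hz: ", nFallback,
              " pixel(s) fell back to the block median")
  }
  res
}

.rowExtreme <- function(m, fun) {
  if (identical(fun, min)) do.call(pmin, c(asplit(m, 2), na.rm = TRUE))
  else do.call(pmax, c(asplit(m, 2), na.rm = TRUE))
}
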