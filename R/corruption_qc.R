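#' Detect MRI-corrupted sinogram frames
#'
#' For each frame the residual against the nominal per-channel values of
#' its wavelength group is computed, and the frame is flagged as corrupted
#' when the L1 norm of that residual exceeds the threshold. Nominal values
#' are the per-channel, per-sample median across all frames of the same
#' wavelength (the median resists contamination by the corruption itself),
#' and the threshold is estimated per wavelength.
#'
#' Frames containing non-finite samples are flagged unconditionally.
#'
#' @param stream a [SinogramStream-class].
#' @param thresholdPolicy "mad" (default): tau = median(L1) + nMad *
#'   MAD(L1) per wavelength; "fixed": use \code{tau} as an absolute
#'   threshold for every wavelength.
#' @param nMad multiplier of the scaled MAD for the "mad" policy.
#' @param tau absolute threshold for the "fixed" policy.
#' @return a [CorruptionReport-class] with mask, per-frame residual L1
#'   norms and the threshold(s) used.
#' @export
detectCorrupted <- function(stream, thresholdPolicy = c("mad", "fixed"),
                            nMad = 5, tau = NULL) {
  thresholdPolicy <- match.arg(thresholdPolicy)
  if (thresholdPolicy == "fixed" && is.null(tau))
    stop("fixed threshold policy requires tau")
  d <- stream@data
  n <- nFrames(stream)
  wl <- stream@wavelengthNm
  nPix <- dim(d)[1] * dim(d)[2]
  resid <- numeric(n)
  nonfinite <- logical(n)
  thr <- c()
  mask <- logical(n)
  for (w in sort(unique(wl))) {
    idx <- which(wl == w)
    if (length(idx) < 10L)
      stop("need at least 10 frames per wavelength to estimate nominal ",
           "values (", w, " nm has ", length(idx), ")")
    m <- matrix(d[, , idx], nPix, length(idx))
    bad <- colSums(!is.finite(m)) > 0
    nonfinite[idx[bad]] <- TRUE
    nominal <- .rowMedians(ifelse(is.finite(m), m, NA_real_))
    r <- colSums(abs(m - nominal), na.rm = TRUE)
    resid[idx] <- r
    tw <- if (thresholdPolicy == "mad")
      stats::median(r) + nMad * stats::mad(r)
    else tau
    thr[as.character(w)] <- tw
    mask[idx] <- r > tw
  }
  mask <- mask | nonfinite
  if (all(mask) && n > 0)
    warning("every frame flagged as corrupted; threshold likely ",
            "misconfigured")
  new("CorruptionReport", mask = mask, residualL1 = resid, threshold = thr,
      wavelengthNm = wl, timestampS = stream@timestampS,
      intensityMap = data.frame(), spectrum = data.frame(),
      peakFrequencyHz = NA_real_)
}

# Row-wise medians via the grouped-sort trick (no per-row apply).
# NAs are ignored; an all-NA row yields NA.
.rowMedians <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  if (nc == 1L) return(as.numeric(m))
  nas <- is.na(m)
  if (any(nas)) m[nas] <- Inf  # sorts last within each row
  o <- order(row(m), m)
  s <- matrix(m[o], nr, nc, byrow = TRUE)
  nOk <- nc - rowSums(nas)
  lo <- pmax((nOk + 1L) %/% 2L, 1L)
  hi <- pmax(nOk %/% 2L + 1L, 1L)
  res <- (s[cbind(seq_len(nr), lo)] + s[cbind(seq_len(nr), hi)]) / 2
  res[nOk == 0L] <- NA_real_
  res
}

#' Temporal corruption intensity map
#'
#' Number of corrupted frames per time bin (1 s by default).
#'
#' @param mask per-frame corruption flags, or a [CorruptionReport-class].
#' @param timestampS per-frame timestamps (ignored when a report is
#'   given).
#' @param binS bin width in seconds.
#' @return data.frame with columns timeS (bin start) and count.
#' @export
corruptionIntensityMap <- function(mask, timestampS = NULL, binS = 1.0) {
  if (is(mask, "CorruptionReport")) {
    timestampS <- mask@timestampS
    mask <- mask@mask
  }
  if (!length(mask))
    return(data.frame(timeS = numeric(), count = integer()))
  if (is.unsorted(timestampS)) stop("timestamps must be monotone increasing")
  edges <- seq(0, max(timestampS) + binS, by = binS)
  bin <- findInterval(timestampS, edges)
  counts <- tabulate(bin[mask], nbins = length(edges) - 1L)
  data.frame(timeS = edges[-length(edges)], count = counts)
}

#' Corruption power spectrum
#'
#' Discrete Fourier transform of the 0/1 corrupted-frame indicator sampled
#' at the frame rate. The spectral peak is searched on the one-sided
#' spectrum below Nyquist with the DC bin excluded; ties break toward the
#' lower frequency. A constant indicator has no defined peak and returns
#' \code{NA} with all non-DC power zero.
#'
#' @param mask per-frame 0/1 indicator (logical or numeric), or a
#'   [CorruptionReport-class].
#' @param frameRateHz sampling rate of the indicator (frames per second).
#' @return list with \code{frequencyHz}, \code{power},
#'   \code{peakFrequencyHz} (NA when undefined).
#' @export
corruptionSpectrum <- function(mask, frameRateHz = 50) {
  if (is(mask, "CorruptionReport")) {
    fr <- 1 / stats::median(diff(mask@timestampS))
    if (missing(frameRateHz)) frameRateHz <- fr
    mask <- mask@mask
  }
  x <- as.numeric(mask)
  n <- length(x)
  if (n < 2 * frameRateHz)
    stop("need at least 2 s of data (", ceiling(2 * frameRateHz),
         " frames) for a spectrum")
  X <- stats::fft(x)
  nHalf <- floor(n / 2) + 1L
  freq <- (seq_len(nHalf) - 1) * frameRateHz / n
  pow <- Mod(X[seq_len(nHalf)])^2 / n
  nonDc <- pow[-1]
  peak <- if (max(nonDc) <= .Machine$double.eps * n) NA_real_
  else freq[which.max(nonDc) + 1L]
  list(frequencyHz = freq, power = pow, peakFrequencyHz = peak)
}

#' Full corruption QC report
#'
#' Runs [detectCorrupted()] and fills in the intensity map and corruption
#' spectrum slots.
#'
#' @inheritParams detectCorrupted
#' @param binS intensity-map bin width (s).
#' @return a [CorruptionReport-class] with all slots populated.
#' @export
corruptionQC <- function(stream, thresholdPolicy = c("mad", "fixed"),
                         nMad = 5, tau = NULL, binS = 1.0) {
  rep <- detectCorrupted(stream, thresholdPolicy, nMad = nMad, tau = tau)
  rep@intensityMap <- corruptionIntensityMap(rep, binS = binS)
  sp <- corruptionSpectrum(rep@mask, frameRateHz = stream@prfHz)
  rep@spectrum <- data.frame(frequencyHz = sp$frequencyHz, power = sp$power)
  rep@peakFrequencyHz <- sp$peakFrequencyHz
  rep
}
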