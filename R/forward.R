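#' Simulate a single optoacoustic sinogram
#'
#' Analytic forward model: every spherical absorber emits the classical
#' bipolar N-shaped transient of a uniformly absorbing sphere, centred at
#' its acoustic time of flight to each element, with peak amplitude
#' proportional to its absorption coefficient and sphere radius and
#' decaying as one over distance. Signals are evaluated on a temporally
#' oversampled axis, band-limited with the detection band (the transducer
#' response model), and decimated to the DAQ rate; seeded Gaussian noise
#' is then added per sample.
#'
#' A uniform background absorption generates no interior acoustic
#' transient in this idealized model and is ignored by the acoustic
#' forward operator.
#'
#' @param phantom a [Phantom-class].
#' @param geometry an [ArrayGeometry-class].
#' @param sosModel a [TwoRegionSOSModel-class].
#' @param wavelengthNm excitation wavelength; must be tabulated in the
#'   phantom.
#' @param noiseSd standard deviation of additive Gaussian noise.
#' @param seed integer seed for the noise draw (\code{NULL} leaves the RNG
#'   state alone).
#' @param pulseEnergyMj laser pulse energy; signal amplitudes scale with
#'   it.
#' @param timestampS,frameIndex frame tags.
#' @param oversample temporal oversampling factor of the forward
#'   evaluation.
#' @param bandlimit apply the detection band (recommended; the raw N-wave
#'   of a 40 um sphere is sub-sample at 40 Msps).
#' @return a [SinogramFrame-class].
#' @export
simulateSinogram <- function(phantom, geometry, sosModel = uniformSos(1400),
                             wavelengthNm = 800, noiseSd = 0, seed = NULL,
                             pulseEnergyMj = 1, timestampS = 0,
                             frameIndex = 1L, oversample = 4L,
                             bandlimit = TRUE) {
  iw <- match(wavelengthNm, phantom@wavelengthsNm)
  if (is.na(iw) && nrow(phantom@absorbers) > 0)
    stop("phantom has no absorption tabulated at ", wavelengthNm, " nm")
  clean <- .forwardClean(phantom, geometry, sosModel, iw, oversample,
                         bandlimit)
  data <- clean * pulseEnergyMj
  if (noiseSd > 0) {
    if (!is.null(seed)) set.seed(seed)
    data <- data + stats::rnorm(length(data), sd = noiseSd)
  }
  new("SinogramFrame", data = data, wavelengthNm = wavelengthNm,
      timestampS = timestampS, pulseEnergyMj = pulseEnergyMj,
      frameIndex = as.integer(frameIndex))
}

# Noise-free, unit-energy forward model for one wavelength index.
.forwardClean <- function(phantom, geometry, sosModel, iw,
                          oversample = 4L, bandlimit = TRUE) {
  nCh <- nChannels(geometry)
  nS <- geometry@nSamples
  fs <- geometry@samplingRate
  os <- as.integer(oversample)
  fsH <- fs * os
  nH <- nS * os
  tH <- geometry@delayS + (seq_len(nH) - 1) / fsH
  sig <- matrix(0, nCh, nH)
  pos <- geometry@positions
  ab <- phantom@absorbers
  for (k in seq_len(nrow(ab))) {
    mu <- phantom@absorption[k, iw]
    if (mu == 0) next
    ctr <- c(ab$x[k], ab$y[k], ab$z[k])
    a <- ab$radiusMm[k]
    tof <- timeOfFlight(pos, ctr, sosModel)
    dMm <- sqrt(colSums((t(pos) - ctr)^2))
    cEff <- dMm * 1e-3 / tof          # effective straight-ray speed (m/s)
    halfS <- a * 1e-3 / cEff          # N-wave half-duration (s)
    tWin <- range(tH)
    if (any(tof - halfS < tWin[1] | tof + halfS > tWin[2]))
      warning("absorber ", k, ": time of flight partly outside the ",
              "recorded window; contribution truncated")
    # p(t) = mu * c_eff (tof - t) / (2 d) inside |t - tof| <= a / c_eff
    dt <- outer(tof, tH, "-")                        # nCh x nH
    inside <- abs(dt) <= halfS
    amp <- (cEff * 1e3) / (2 * dMm) * mu             # per-mm scaling
    sig <- sig + amp * dt * inside
  }
  if (bandlimit && any(sig != 0))
    sig <- .bandpassRows(sig, geometry@bandpassHz[1], geometry@bandpassHz[2],
                         fsH)
  sig[, seq(1, nH, by = os), drop = FALSE]
}

#' Simulate an interleaved multi-wavelength sinogram stream
#'
#' Generates \code{durationS * prfHz} frames cycling through the
#' configured wavelengths on a per-pulse basis. With \code{hemo} supplied
#' (output of [simulateParadigmHemodynamics()]) and a phantom carrying
#' per-absorber \code{so2}/\code{hbt} columns (see [hemoglobinPhantom()]),
#' absorber absorption follows its compartment's hemodynamic trace second
#' by second; otherwise the phantom is static and the clean frame per
#' wavelength is computed once.
#'
#' @param phantom a [Phantom-class].
#' @param geometry an [ArrayGeometry-class].
#' @param timing an [AcquisitionTiming-class].
#' @param sosModel a [TwoRegionSOSModel-class].
#' @param noiseSd additive Gaussian noise standard deviation.
#' @param seed integer seed.
#' @param hemo optional hemodynamics data.frame (1 Hz).
#' @param pulseEnergyMj pulse energy, scalar or one value per wavelength.
#' @return a [SinogramStream-class].
#' @export
simulateStream <- function(phantom, geometry, timing = acquisitionTiming(),
                           sosModel = uniformSos(1400), noiseSd = 0,
                           seed = NULL, hemo = NULL, pulseEnergyMj = 1) {
  if (!is.null(seed)) set.seed(seed)
  nFrames <- as.integer(round(timing@durationS * timing@prfHz))
  wl <- rep_len(timing@wavelengthsNm, nFrames)
  ts <- (seq_len(nFrames) - 1) / timing@prfHz
  energy <- rep_len(pulseEnergyMj, length(timing@wavelengthsNm))
  energyOfFrame <- energy[match(wl, timing@wavelengthsNm)]
  nCh <- nChannels(geometry)
  nS <- geometry@nSamples
  data <- array(0, c(nCh, nS, nFrames))
  if (is.null(hemo)) {
    for (w in seq_along(timing@wavelengthsNm)) {
      iw <- match(timing@wavelengthsNm[w], phantom@wavelengthsNm)
      clean <- if (nrow(phantom@absorbers) && !is.na(iw))
        .forwardClean(phantom, geometry, sosModel, iw)
      else matrix(0, nCh, nS)
      idx <- which(wl == timing@wavelengthsNm[w])
      for (f in idx) data[, , f] <- clean * energyOfFrame[f]
    }
  } else {
    sec <- pmin(floor(ts), max(hemo$timeS))
    for (s in unique(sec)) {
      ph <- .phantomAtTime(phantom, hemo, s)
      for (w in seq_along(timing@wavelengthsNm)) {
        iw <- match(timing@wavelengthsNm[w], ph@wavelengthsNm)
        idx <- which(wl == timing@wavelengthsNm[w] & sec == s)
        if (!length(idx)) next
        clean <- if (nrow(ph@absorbers) && !is.na(iw))
          .forwardClean(ph, geometry, sosModel, iw)
        else matrix(0, nCh, nS)
        for (f in idx) data[, , f] <- clean * energyOfFrame[f]
      }
    }
  }
  if (noiseSd > 0)
    data <- data + array(stats::rnorm(length(data), sd = noiseSd), dim(data))
  new("SinogramStream", data = data, wavelengthNm = wl, timestampS = ts,
      pulseEnergyMj = energyOfFrame, geometry = geometry,
      prfHz = timing@prfHz, corruptMask = NULL)
}

# Phantom with absorber absorption re-evaluated from its compartment's
# hemodynamic state at time s.
.phantomAtTime <- function(phantom, hemo, s) {
  ab <- phantom@absorbers
  if (!all(c("hbt") %in% names(ab))) return(phantom)
  mu <- phantom@absorption
  for (k in seq_len(nrow(ab))) {
    tr <- hemo[hemo$compartment == ab$compartment[k], ]
    if (!nrow(tr)) next
    i <- which.min(abs(tr$timeS - s))
    mu[k, ] <- hemoglobinAbsorption(tr$so2[i], ab$hbt[k],
                                    phantom@wavelengthsNm)
  }
  phantom@absorption <- mu
  phantom
}

#' Inject MRI slice-excitation interference into a stream
#'
#' Lays out BOLD slice-excitation events at \code{boldSlices} equally
#' spaced instants per TR (with optional Gaussian jitter) and corrupts
#' every frame whose acquisition window overlaps an event with additive
#' high-amplitude bipolar bursts on a random channel subset spanning a
#' random sample interval. The acquisition window defaults to the full
#' frame repetition period, the resolution at which a frame is kept or
#' discarded downstream.
#'
#' @param stream a [SinogramStream-class].
#' @param timing an [AcquisitionTiming-class] carrying the BOLD TR and
#'   slice count.
#' @param burstAmplitude burst amplitude (0 marks the mask without
#'   touching the data).
#' @param burstChannelFraction fraction of channels hit per burst, in
#'   (0, 1].
#' @param jitterSd Gaussian jitter of event times (s).
#' @param seed integer seed.
#' @param windowS acquisition window per frame (s); default 1 / PRF.
#' @param eventTimesS explicit event times overriding the TR layout.
#' @return list with elements \code{stream} (corrupted copy, with
#'   \code{corruptMask} set) and \code{mask} (ground-truth logical).
#' @export
injectMriCorruption <- function(stream, timing = acquisitionTiming(),
                                burstAmplitude = 1,
                                burstChannelFraction = 0.25, jitterSd = 0,
                                seed = NULL, windowS = NULL,
                                eventTimesS = NULL) {
  if (burstAmplitude < 0) stop("burstAmplitude must be >= 0")
  if (burstChannelFraction <= 0 || burstChannelFraction > 1)
    stop("burstChannelFraction must lie in (0, 1]")
  if (jitterSd < 0) stop("jitterSd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  ts <- stream@timestampS
  n <- nFrames(stream)
  if (is.null(windowS)) windowS <- 1 / stream@prfHz
  if (is.null(eventTimesS)) {
    dur <- max(ts) + windowS
    nTr <- ceiling(dur / timing@boldTrS)
    ev <- as.vector(outer((seq_len(timing@boldSlices) - 1) *
                            timing@boldTrS / timing@boldSlices,
                          (seq_len(nTr) - 1) * timing@boldTrS, "+"))
    ev <- sort(ev[ev < dur])
  } else ev <- sort(eventTimesS)
  if (jitterSd > 0) ev <- ev + stats::rnorm(length(ev), sd = jitterSd)
  idx <- findInterval(ev, ts)
  hit <- idx >= 1 & idx <= n
  hit[hit] <- ev[hit] < ts[idx[hit]] + windowS
  mask <- rep(FALSE, n)
  mask[idx[hit]] <- TRUE
  if (burstAmplitude > 0 && any(mask)) {
    # modify a local copy so the large array is not re-copied per frame
    data <- stream@data
    nCh <- dim(data)[1]
    nS <- dim(data)[2]
    nHit <- max(1L, ceiling(burstChannelFraction * nCh))
    for (f in which(mask)) {
      ch <- sample.int(nCh, nHit)
      s0 <- sample.int(nS, 1)
      s1 <- min(nS, s0 + sample.int(max(1L, nS %/% 4L), 1) - 1L)
      len <- s1 - s0 + 1L
      burst <- burstAmplitude * rep_len(c(1, -1), len) *
        sign(stats::runif(1) - 0.5)
      data[ch, s0:s1, f] <- data[ch, s0:s1, f] +
        matrix(burst, nHit, len, byrow = TRUE)
    }
    stream@data <- data
  }
  stream@corruptMask <- mask
  list(stream = stream, mask = mask)
}
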