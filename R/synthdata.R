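#' Build a hemispherical detection array
#'
#' Places \code{nElements} detector elements quasi-uniformly on a spherical
#' cap of the given radius and angular aperture using a Fibonacci lattice.
#' The cap is centred on the array symmetry axis (the -z pole; the z axis
#' points from the array centre into the tissue). Placement is
#' deterministic for fixed arguments.
#'
#' The default acquisition delay is chosen so that the arrival from the
#' centre of the field of view (one sphere radius away, at the water speed
#' of sound 1400 m/s) falls at the middle of the recorded window.
#'
#' @param nElements number of detector elements.
#' @param radiusMm sphere radius in mm.
#' @param apertureDeg full angular aperture of the cap in degrees.
#' @param samplingRate DAQ sampling rate (samples/s).
#' @param nSamples samples per recorded frame.
#' @param centerFrequencyHz transducer centre frequency (Hz).
#' @param bandpassHz detection band, low/high cut (Hz).
#' @param delayS acquisition pre-trigger delay (s); \code{NULL} for the
#'   default mid-window placement.
#' @return an [ArrayGeometry-class].
#' @examples
#' geom <- buildHemisphericalArray()
#' nChannels(geom)
#' range(sqrt(rowSums(elementPositions(geom)^2)))
#' @export
buildHemisphericalArray <- function(nElements = 384L, radiusMm = 40,
                                    apertureDeg = 130, samplingRate = 40e6,
                                    nSamples = 494L,
                                    centerFrequencyHz = 5e6,
                                    bandpassHz = c(0.1e6, 8e6),
                                    delayS = NULL) {
  if (radiusMm <= 0) stop("radiusMm must be positive")
  if (samplingRate <= 0) stop("samplingRate must be positive")
  if (nElements < 1L) stop("nElements must be >= 1")
  if (apertureDeg <= 0 || apertureDeg > 180)
    stop("apertureDeg must lie in (0, 180]")
  n <- as.integer(nElements)
  thetaMax <- apertureDeg / 2 * pi / 180
  if (n == 1L) {
    pos <- matrix(c(0, 0, -radiusMm), 1, 3)
  } else {
    # Fibonacci lattice restricted to the cap: cos(theta) uniform on
    # [cos(thetaMax), 1], azimuth stepped by the golden angle.
    i <- seq_len(n) - 0.5
    u <- 1 - i / n * (1 - cos(thetaMax))
    theta <- acos(pmin(1, u))
    golden <- pi * (3 - sqrt(5))
    phi <- (seq_len(n) - 1) * golden
    pos <- radiusMm * cbind(sin(theta) * cos(phi),
                            sin(theta) * sin(phi),
                            -cos(theta))
  }
  if (is.null(delayS))
    delayS <- radiusMm * 1e-3 / 1400 - (nSamples / 2) / samplingRate
  new("ArrayGeometry", positions = pos, radiusMm = radiusMm,
      apertureDeg = apertureDeg, samplingRate = samplingRate,
      nSamples = as.integer(nSamples),
      centerFrequencyHz = centerFrequencyHz, bandpassHz = bandpassHz,
      delayS = delayS)
}

#' Construct an array geometry from explicit element positions
#'
#' Used for custom layouts (e.g. mirror-symmetric element pairs in symmetry
#' tests); positions must lie on the stated sphere within tolerance.
#'
#' @param positions n x 3 matrix of element centres (mm).
#' @inheritParams buildHemisphericalArray
#' @return an [ArrayGeometry-class].
#' @export
arrayGeometry <- function(positions, radiusMm = 40, apertureDeg = 130,
                          samplingRate = 40e6, nSamples = 494L,
                          centerFrequencyHz = 5e6,
                          bandpassHz = c(0.1e6, 8e6), delayS = NULL) {
  if (is.null(delayS))
    delayS <- radiusMm * 1e-3 / 1400 - (nSamples / 2) / samplingRate
  new("ArrayGeometry", positions = as.matrix(positions), radiusMm = radiusMm,
      apertureDeg = apertureDeg, samplingRate = samplingRate,
      nSamples = as.integer(nSamples),
      centerFrequencyHz = centerFrequencyHz, bandpassHz = bandpassHz,
      delayS = delayS)
}

#' Construct an absorption phantom
#'
#' @param absorbers data.frame with columns x, y, z (mm), radiusMm,
#'   compartment ("vessel"/"parenchyma").
#' @param absorption matrix (absorbers x wavelengths) of absorption
#'   coefficients, or a vector recycled across wavelengths.
#' @param wavelengthsNm wavelengths the absorption columns refer to.
#' @param background background absorption per wavelength.
#' @return a [Phantom-class].
#' @export
phantom <- function(absorbers = data.frame(x = numeric(), y = numeric(),
                                           z = numeric(),
                                           radiusMm = numeric(),
                                           compartment = character()),
                    absorption = matrix(0, nrow(absorbers),
                                        length(wavelengthsNm)),
                    wavelengthsNm = c(700, 730, 755, 800, 850),
                    background = rep(0, length(wavelengthsNm))) {
  if (is.vector(absorption) && !is.matrix(absorption))
    absorption <- matrix(absorption, nrow(absorbers), length(wavelengthsNm))
  new("Phantom", absorbers = absorbers, absorption = as.matrix(absorption),
      background = background, wavelengthsNm = wavelengthsNm)
}

#' Two-compartment hemoglobin phantom
#'
#' Spherical absorbers whose per-wavelength absorption follows the shipped
#' hemoglobin extinction spectra at the given oxygen saturations: the
#' standard fixture for end-to-end unmixing checks.
#'
#' @param centers n x 3 matrix of sphere centres (mm).
#' @param radiiMm sphere radii (mm).
#' @param compartment per-sphere labels, "vessel" or "parenchyma".
#' @param so2 per-sphere oxygen saturation.
#' @param hbt per-sphere total hemoglobin (relative units).
#' @param wavelengthsNm excitation wavelengths.
#' @return a [Phantom-class].
#' @export
hemoglobinPhantom <- function(centers, radiiMm, compartment, so2, hbt = 1,
                              wavelengthsNm = c(700, 730, 755, 800, 850)) {
  centers <- matrix(centers, ncol = 3)
  n <- nrow(centers)
  hbt <- rep_len(hbt, n)
  so2 <- rep_len(so2, n)
  ab <- data.frame(x = centers[, 1], y = centers[, 2], z = centers[, 3],
                   radiusMm = rep_len(radiiMm, n),
                   compartment = rep_len(compartment, n),
                   so2 = so2, hbt = hbt)
  mu <- t(vapply(seq_len(n),
                 function(i) hemoglobinAbsorption(so2[i], hbt[i], wavelengthsNm),
                 numeric(length(wavelengthsNm))))
  phantom(ab, mu, wavelengthsNm)
}

#' Construct the breathing-gas stimulation paradigm
#'
#' Defaults reproduce the 15-min oxygen challenge: 3 min baseline at
#' FiO2 = 0.36, then three cycles of 2 min normoxia (0.20) and 2 min
#' hyperoxia (1.00).
#'
#' @param baselineDurationS,nCycles,normoxiaDurationS,hyperoxiaDurationS
#'   segment structure (s).
#' @param fio2Baseline,fio2Normoxia,fio2Hyperoxia inspired O2 fractions.
#' @param airO2Fraction O2 fraction of medical air.
#' @return a [StimulusParadigm-class].
#' @export
stimulusParadigm <- function(baselineDurationS = 180, nCycles = 3L,
                             normoxiaDurationS = 120,
                             hyperoxiaDurationS = 120,
                             fio2Baseline = 0.36, fio2Normoxia = 0.20,
                             fio2Hyperoxia = 1.00, airO2Fraction = 0.20) {
  new("StimulusParadigm", baselineDurationS = baselineDurationS,
      nCycles = as.integer(nCycles), normoxiaDurationS = normoxiaDurationS,
      hyperoxiaDurationS = hyperoxiaDurationS, fio2Baseline = fio2Baseline,
      fio2Normoxia = fio2Normoxia, fio2Hyperoxia = fio2Hyperoxia,
      airO2Fraction = airO2Fraction)
}

#' Construct the acquisition timing
#'
#' Defaults follow the in vivo protocol: 50 Hz PRF swept over five
#' wavelengths (so 10 Hz per wavelength), concurrent BOLD EPI with 11
#' slices per 995 ms TR, 900 s total.
#'
#' @param prfHz laser pulse repetition frequency (Hz).
#' @param wavelengthsNm swept excitation wavelengths (nm).
#' @param boldTrS BOLD repetition time (s).
#' @param boldSlices slices per BOLD volume.
#' @param durationS acquisition duration (s).
#' @return an [AcquisitionTiming-class].
#' @export
acquisitionTiming <- function(prfHz = 50, wavelengthsNm = c(700, 730, 755,
                                                            800, 850),
                              boldTrS = 0.995, boldSlices = 11L,
                              durationS = 900) {
  new("AcquisitionTiming", prfHz = prfHz, wavelengthsNm = wavelengthsNm,
      boldTrS = boldTrS, boldSlices = as.integer(boldSlices),
      durationS = durationS)
}

#' Inspired oxygen fraction of an oxygen/air mixture
#'
#' FiO2 of a gas mixture delivered as pure oxygen at \code{o2Flow} mixed
#' with medical air at \code{airFlow}:
#' (o2Flow + airFlow * airO2Fraction) / (o2Flow + airFlow).
#'
#' @param o2Flow oxygen flow (any consistent unit, e.g. mL/min).
#' @param airFlow air flow (same unit).
#' @param airO2Fraction oxygen fraction of air.
#' @return FiO2 as a fraction in (0, 1].
#' @examples
#' fio2OfMixture(200, 800)  # the 36% baseline mixture
#' @export
fio2OfMixture <- function(o2Flow, airFlow, airO2Fraction = 0.20) {
  if (o2Flow < 0 || airFlow < 0) stop("flows must be non-negative")
  if (o2Flow + airFlow == 0) stop("at least one flow must be positive")
  (o2Flow * 1.0 + airFlow * airO2Fraction) / (o2Flow + airFlow)
}

#' Inspired-O2 time course of a paradigm
#'
#' Step-wise FiO2 trace sampled at \code{dtS} spacing (sample k covers
#' time [(k-1) dt, k dt)).
#'
#' @param paradigm a [StimulusParadigm-class].
#' @param dtS sample spacing (s).
#' @return numeric vector of length totalDuration/dtS.
#' @export
fio2Trace <- function(paradigm, dtS = 1) {
  tt <- seq(0, totalDuration(paradigm) - dtS, by = dtS)
  f <- rep(paradigm@fio2Baseline, length(tt))
  cyc <- paradigm@normoxiaDurationS + paradigm@hyperoxiaDurationS
  for (k in seq_len(paradigm@nCycles)) {
    t0 <- paradigm@baselineDurationS + (k - 1) * cyc
    f[tt >= t0 & tt < t0 + paradigm@normoxiaDurationS] <- paradigm@fio2Normoxia
    f[tt >= t0 + paradigm@normoxiaDurationS & tt < t0 + cyc] <-
      paradigm@fio2Hyperoxia
  }
  f
}

#' Cycle windows of a paradigm
#'
#' Start/end times (s) of each stimulation cycle (normoxia + hyperoxia
#' segment; the baseline is excluded).
#'
#' @param paradigm a [StimulusParadigm-class].
#' @return data.frame with columns cycle, startS, endS.
#' @export
cycleWindows <- function(paradigm) {
  cyc <- paradigm@normoxiaDurationS + paradigm@hyperoxiaDurationS
  start <- paradigm@baselineDurationS + (seq_len(paradigm@nCycles) - 1) * cyc
  data.frame(cycle = seq_len(paradigm@nCycles), startS = start,
             endS = start + cyc)
}

#' Simulate paradigm-driven compartment hemodynamics
#'
#' Generates 1 Hz HbO/HbR/HbT/sO2 traces for vessel and parenchyma
#' compartments responding to the inspired-O2 paradigm. Oxygen saturation
#' tracks FiO2 linearly (per-compartment gain) through first-order
#' exponential kinetics with time constant \code{tauS}; total hemoglobin is
#' held exactly constant per compartment, so HbO + HbR is conserved to
#' machine precision by construction. Seeded Gaussian noise is added to the
#' saturation trace.
#'
#' @param paradigm a [StimulusParadigm-class].
#' @param compartments data.frame with columns label, so2Baseline, gain
#'   (saturation change per unit FiO2 change) and hbt. Vessel responses are
#'   conventionally stronger than parenchymal ones (default gains 0.25 vs
#'   0.10).
#' @param tauS transition time constant (s).
#' @param noiseSd standard deviation of the saturation noise.
#' @param seed integer seed.
#' @param dtS sample spacing (s).
#' @return data.frame with columns timeS, compartment, so2, hbo, hbr, hbt.
#' @examples
#' h <- simulateParadigmHemodynamics(stimulusParadigm(), seed = 1)
#' aggregate(hbt ~ compartment, h, function(x) diff(range(x)))
#' @export
simulateParadigmHemodynamics <- function(paradigm = stimulusParadigm(),
                                         compartments = data.frame(
                                           label = c("vessel", "parenchyma"),
                                           so2Baseline = c(0.80, 0.70),
                                           gain = c(0.25, 0.10),
                                           hbt = c(1.0, 0.35)),
                                         tauS = 10, noiseSd = 0,
                                         seed = NULL, dtS = 1) {
  stopifnot(all(c("label", "so2Baseline", "gain", "hbt") %in%
                  names(compartments)))
  if (any(compartments$gain < 0)) stop("response gains must be >= 0")
  if (any(compartments$hbt <= 0)) stop("hbt must be positive")
  if (tauS <= 0) stop("tauS must be positive")
  if (!is.null(seed)) set.seed(seed)
  fio2 <- fio2Trace(paradigm, dtS)
  nt <- length(fio2)
  alpha <- 1 - exp(-dtS / tauS)
  out <- vector("list", nrow(compartments))
  for (i in seq_len(nrow(compartments))) {
    cp <- compartments[i, ]
    target <- pmin(1, pmax(0, cp$so2Baseline + cp$gain *
                             (fio2 - paradigm@fio2Baseline)))
    s <- numeric(nt)
    s[1] <- target[1]
    for (k in 2:nt) s[k] <- s[k - 1] + alpha * (target[k] - s[k - 1])
    if (noiseSd > 0)
      s <- pmin(1, pmax(0, s + stats::rnorm(nt, sd = noiseSd)))
    out[[i]] <- data.frame(timeS = (seq_len(nt) - 1) * dtS,
                           compartment = cp$label, so2 = s,
                           hbo = cp$hbt * s, hbr = cp$hbt * (1 - s),
                           hbt = cp$hbt)
  }
  do.call(rbind, out)
}
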