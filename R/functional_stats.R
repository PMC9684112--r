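#' Cubic region-of-interest specification
#'
#' @param centerMm ROI centre in the reconstruction frame (mm).
#' @param edgeMm cube edge length (mm), default 0.4.
#' @param label "vessel" or "parenchyma" (free-form allowed).
#' @return list of class "ROISpec".
#' @export
roiSpec <- function(centerMm, edgeMm = 0.4, label = "vessel") {
  structure(list(centerMm = as.numeric(centerMm), edgeMm = edgeMm,
                 label = label), class = "ROISpec")
}

#' Extract an ROI time course from a 4-D series
#'
#' Mean over all voxels inside the ROI cube at each time point; NA-masked
#' voxels are excluded.
#'
#' @param series a [VolumeSeries-class], [HemoSeries-class] component
#'   (select with \code{component}), or 4-D array with a \code{grid}.
#' @param roi an ROI from [roiSpec()].
#' @param component for a [HemoSeries-class]: one of "hbo", "hbr",
#'   "hbt", "so2".
#' @param grid required when \code{series} is a plain array.
#' @return numeric time series.
#' @export
roiTimecourse <- function(series, roi, component = "hbo", grid = NULL) {
  if (is(series, "HemoSeries")) {
    grid <- series@grid
    arr <- slot(series, component)
  } else if (is(series, "VolumeSeries")) {
    grid <- series@grid
    arr <- series@values
  } else arr <- series
  if (is.null(grid)) stop("grid is required for a plain array")
  half <- roi$edgeMm / 2
  sel <- lapply(1:3, function(a) {
    ctr <- grid@originMm[a] + (seq_len(grid@dim[a]) - 0.5) *
      grid@voxelSizeMm[a]
    which(ctr >= roi$centerMm[a] - half & ctr <= roi$centerMm[a] + half)
  })
  if (any(vapply(sel, length, 1L) == 0L))
    stop("ROI cube lies outside the grid")
  sub <- arr[sel[[1]], sel[[2]], sel[[3]], , drop = FALSE]
  tc <- apply(sub, 4, mean, na.rm = TRUE)
  if (all(is.nan(tc))) stop("ROI is fully masked")
  tc
}

#' Fractional signal change
#'
#' dS/S = (S(t) - BL) / BL with BL the mean over the initial baseline
#' window.
#'
#' @param series numeric series sampled at \code{dtS} spacing.
#' @param baselineWindowS baseline duration (s), default 180.
#' @param dtS sample spacing (s).
#' @return dS/S series.
#' @export
fractionalChange <- function(series, baselineWindowS = 180, dtS = 1) {
  nb <- round(baselineWindowS / dtS)
  if (nb < 1 || nb > length(series))
    stop("series does not cover the baseline window")
  bl <- mean(series[seq_len(nb)], na.rm = TRUE)
  if (!is.finite(bl) || bl == 0)
    stop("baseline mean is zero; fractional change undefined")
  (series - bl) / bl
}

#' Zero-phase Butterworth low-pass smoothing
#'
#' Low-pass with the stated normalized half-power frequency (on the
#' Nyquist-normalized axis of the series; 0.15 at 1 Hz sampling means
#' 0.075 Hz). The filter is applied forward-backward, and the single-pass
#' cutoff is pre-warped so the net zero-phase response has gain 1/sqrt(2)
#' at the requested frequency; DC gain is 1.
#'
#' @param series numeric series.
#' @param normalizedHalfPower half-power frequency on the [0, 1] Nyquist
#'   axis (default 0.15).
#' @param order single-pass Butterworth order (default 4).
#' @return smoothed series.
#' @export
smoothTimecourse <- function(series, normalizedHalfPower = 0.15,
                             order = 4L) {
  if (length(series) <= 3 * order)
    stop("series too short for the filter (need > ", 3 * order,
         " samples)")
  # forward-backward squares the magnitude response: place the
  # single-pass cutoff so |H|^2 = 1/sqrt(2) at the requested frequency,
  # pre-warping on the bilinear (tan) axis of the digital design
  ratio <- (sqrt(2) - 1)^(1 / (2 * order))
  wc <- 2 / pi * atan(tan(pi * normalizedHalfPower / 2) / ratio)
  bf <- signal::butter(order, wc, type = "low")
  # odd-reflection padding suppresses the start/end transients
  n <- length(series)
  p <- min(n - 1L, ceiling(6 / wc))
  xp <- c(2 * series[1] - series[(p + 1):2],
          series,
          2 * series[n] - series[(n - 1):(n - p)])
  y <- signal::filtfilt(bf, xp)
  as.numeric(y[(p + 1):(p + n)])
}

#' Per-cycle response amplitudes
#'
#' Maximum absolute fractional signal change within each stimulation
#' cycle (the cycle's normoxia + hyperoxia window; the baseline is
#' excluded).
#'
#' @param dss dS/S series sampled at \code{dtS}.
#' @param paradigm a [StimulusParadigm-class].
#' @param dtS sample spacing (s).
#' @return numeric vector, one amplitude per cycle.
#' @export
responseAmplitudes <- function(dss, paradigm = stimulusParadigm(),
                               dtS = 1) {
  tt <- (seq_along(dss) - 1) * dtS
  win <- cycleWindows(paradigm)
  if (max(win$endS) - dtS > max(tt))
    stop("cycle windows extend beyond the series")
  vapply(seq_len(nrow(win)), function(k) {
    sel <- tt >= win$startS[k] & tt < win$endS[k]
    max(abs(dss[sel]), na.rm = TRUE)
  }, numeric(1))
}

#' Compare response amplitudes between two components
#'
#' Two-sample two-tailed t-test (pooled variance by default; Welch via
#' \code{welch = TRUE}) between two groups of response amplitudes, with
#' significance flagged at the given alpha. Two groups with zero variance
#' and equal means return p = 1 by convention.
#'
#' @param a,b numeric amplitude groups (n >= 2 each).
#' @param welch use the Welch unequal-variance test.
#' @param alpha significance level (default 0.05).
#' @return list with t, p, significant, and per-group mean/sd/n.
#' @export
compareComponents <- function(a, b, welch = FALSE, alpha = 0.05) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  summary <- data.frame(group = c("a", "b"), mean = c(mean(a), mean(b)),
                        sd = c(stats::sd(a), stats::sd(b)),
                        n = c(length(a), length(b)))
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, p = 1, significant = FALSE, summary = summary))
    return(list(t = Inf * sign(mean(a) - mean(b)), p = 0,
                significant = TRUE, summary = summary))
  }
  tt <- stats::t.test(a, b, var.equal = !welch,
                      alternative = "two.sided")
  list(t = unname(tt$statistic), p = tt$p.value,
       significant = tt$p.value < alpha, summary = summary)
}

#' Response-amplitude table across components and ROIs
#'
#' Convenience builder of the per-(component, ROI, cycle) amplitude table
#' from a [HemoSeries-class] (and optionally a BOLD [VolumeSeries-class]
#' already resliced to the same frame).
#'
#' @param hemo a [HemoSeries-class].
#' @param rois list of [roiSpec()] ROIs.
#' @param paradigm a [StimulusParadigm-class].
#' @param bold optional BOLD [VolumeSeries-class] on the hemo grid.
#' @param smooth smooth the dS/S series before amplitude extraction
#'   (default FALSE; amplitudes are computed on unsmoothed series).
#' @return data.frame with component, roi, label, cycle, amplitude.
#' @export
responseTable <- function(hemo, rois, paradigm = stimulusParadigm(),
                          bold = NULL, smooth = FALSE) {
  comps <- c("hbo", "hbr", "hbt", "so2")
  out <- list()
  for (ci in comps) for (ri in seq_along(rois)) {
    tc <- roiTimecourse(hemo, rois[[ri]], component = ci)
    # a component clipped to zero (or fully masked) across the ROI has no
    # defined fractional change; skip it rather than abort the table
    dss <- tryCatch(fractionalChange(tc, paradigm@baselineDurationS),
                    error = function(e) {
                      message("responseTable: skipping ", toupper(ci),
                              " in ROI ", ri, ": ", conditionMessage(e))
                      NULL
                    })
    if (is.null(dss)) next
    if (smooth) dss <- smoothTimecourse(dss)
    amp <- responseAmplitudes(dss, paradigm)
    out[[length(out) + 1L]] <- data.frame(
      component = toupper(ci), roi = ri, label = rois[[ri]]$label,
      cycle = seq_along(amp), amplitude = amp)
  }
  if (!is.null(bold)) {
    for (ri in seq_along(rois)) {
      tc <- roiTimecourse(bold, rois[[ri]])
      dss <- fractionalChange(tc, paradigm@baselineDurationS)
      if (smooth) dss <- smoothTimecourse(dss)
      amp <- responseAmplitudes(dss, paradigm)
      out[[length(out) + 1L]] <- data.frame(
        component = "BOLD", roi = ri, label = rois[[ri]]$label,
        cycle = seq_along(amp), amplitude = amp)
    }
  }
  do.call(rbind, out)
}
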