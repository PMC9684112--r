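#' Construct a voxel grid
#'
#' Defaults give the 8 x 8 x 4 mm field of view at 100 um isotropic
#' voxels, centred laterally on the array symmetry axis with the axial
#' range straddling the sphere centre.
#'
#' @param originMm grid corner in mm (voxel centres start half a voxel
#'   inside).
#' @param voxelSizeMm voxel edge lengths (mm), scalar or length 3.
#' @param dim grid dimensions, length 3.
#' @return a [VoxelGrid-class].
#' @export
voxelGrid <- function(originMm = c(-4, -4, -2), voxelSizeMm = 0.1,
                      dim = c(80L, 80L, 40L)) {
  new("VoxelGrid", originMm = as.numeric(originMm),
      voxelSizeMm = rep_len(as.numeric(voxelSizeMm), 3L),
      dim = as.integer(dim))
}

#' Physical coordinates of all voxel centres
#'
#' @param grid a [VoxelGrid-class].
#' @return nVoxels x 3 matrix in mm, in array (column-major) order.
#' @export
voxelCenters <- function(grid) {
  ax <- lapply(1:3, function(a)
    grid@originMm[a] + (seq_len(grid@dim[a]) - 0.5) * grid@voxelSizeMm[a])
  cbind(rep(ax[[1]], times = grid@dim[2] * grid@dim[3]),
        rep(rep(ax[[2]], each = grid@dim[1]), times = grid@dim[3]),
        rep(ax[[3]], each = grid@dim[1] * grid@dim[2]))
}

#' Filtered back-projection reconstruction
#'
#' Volumetric filtered back-projection of one sinogram onto a voxel grid
#' under a uniform or two-region speed-of-sound model. Each voxel
#' accumulates, over all elements with uniform weights, the universal
#' back-projection term b(t) = p(t) - t dp/dt of the (band-passed)
#' channel signal evaluated at the voxel's acoustic time of flight, with
#' linear interpolation between samples. Delays outside the recorded
#' window contribute zero (their count is reported as attribute
#' \code{"nOutOfWindow"} of the values).
#'
#' @param sinogram a [SinogramFrame-class] or plain channels x samples
#'   matrix (already band-passed; use [bandpassSinogram()]).
#' @param geometry an [ArrayGeometry-class].
#' @param sosModel a [TwoRegionSOSModel-class].
#' @param grid a [VoxelGrid-class].
#' @param normalizeEnergy divide by the frame's pulse energy when
#'   available.
#' @return a [ReconVolume-class].
#' @export
fbp <- function(sinogram, geometry, sosModel = uniformSos(1400),
                grid = voxelGrid(), normalizeEnergy = TRUE) {
  if (is(sinogram, "SinogramFrame")) {
    mat <- sinogram@data
    wl <- sinogram@wavelengthNm
    ts <- sinogram@timestampS
    energy <- sinogram@pulseEnergyMj
  } else {
    mat <- as.matrix(sinogram)
    wl <- NA_real_; ts <- NA_real_; energy <- 1
  }
  nCh <- nrow(mat); nS <- ncol(mat)
  if (nCh != nChannels(geometry))
    stop("sinogram channel count does not match the geometry")
  fs <- geometry@samplingRate
  tAx <- geometry@delayS + (seq_len(nS) - 1) / fs
  # universal back-projection term per channel
  dpdt <- t(apply(mat, 1, function(p) {
    d <- numeric(length(p))
    d[2:(nS - 1)] <- (p[3:nS] - p[1:(nS - 2)]) / 2
    d[1] <- p[2] - p[1]; d[nS] <- p[nS] - p[nS - 1]
    d * fs
  }))
  bTerm <- mat - sweep(dpdt, 2, tAx, "*")
  vox <- voxelCenters(grid)
  acc <- numeric(nrow(vox))
  nOut <- 0L
  pos <- geometry@positions
  for (e in seq_len(nCh)) {
    tof <- timeOfFlight(vox, pos[e, ], sosModel)
    u <- (tof - geometry@delayS) * fs + 1
    i0 <- floor(u)
    frac <- u - i0
    ok <- i0 >= 1 & i0 < nS
    nOut <- nOut + sum(!ok)
    i0ok <- i0[ok]
    be <- bTerm[e, ]
    acc[ok] <- acc[ok] + (1 - frac[ok]) * be[i0ok] + frac[ok] * be[i0ok + 1]
  }
  if (normalizeEnergy && is.finite(energy) && energy > 0)
    acc <- acc / energy
  vals <- array(acc / nCh, grid@dim)
  attr(vals, "nOutOfWindow") <- nOut
  new("ReconVolume", grid = grid, values = vals, wavelengthNm = wl,
      timestampS = ts)
}

#' Segment the water/tissue interface from a single-SOS reconstruction
#'
#' From a volume reconstructed with the water speed of sound (superficial
#' structures sharply defined), each (x, y) column is scanned from the
#' water side (increasing z) for the first crossing of a configurable
#' fraction of the column maximum; a low-order surface is least-squares
#' fitted to the column depth estimates.
#'
#' @param volume a [ReconVolume-class] or [ImageVolume-class].
#' @param fraction intensity fraction of the column maximum defining the
#'   crossing (default 0.5).
#' @param fit "plane" (default) or "quadratic".
#' @param minColumnFraction columns whose maximum falls below this
#'   fraction of the global maximum are considered empty.
#' @return interface coefficient list suitable for [twoRegionSos()], with
#'   the per-column depth estimates attached as attribute
#'   \code{"columns"}.
#' @export
segmentInterface <- function(volume, fraction = 0.5,
                             fit = c("plane", "quadratic"),
                             minColumnFraction = 0.1) {
  fit <- match.arg(fit)
  grid <- volume@grid
  v <- abs(volume@values)
  d <- grid@dim
  zAx <- grid@originMm[3] + (seq_len(d[3]) - 0.5) * grid@voxelSizeMm[3]
  colMax <- apply(v, c(1, 2), max)
  gMax <- max(colMax)
  if (gMax == 0 || diff(range(v)) == 0)
    stop("insufficient surface evidence: volume has no contrast")
  xs <- ys <- zs <- numeric(0)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    if (colMax[i, j] < minColumnFraction * gMax || gMax == 0) next
    prof <- v[i, j, ]
    k <- which(prof >= fraction * colMax[i, j])[1]
    xs <- c(xs, grid@originMm[1] + (i - 0.5) * grid@voxelSizeMm[1])
    ys <- c(ys, grid@originMm[2] + (j - 0.5) * grid@voxelSizeMm[2])
    zs <- c(zs, zAx[k])
  }
  if (length(zs) < 10L)
    stop("insufficient surface evidence: only ", length(zs),
         " valid columns (need >= 10)")
  X <- if (fit == "plane") cbind(1, xs, ys)
  else cbind(1, xs, ys, xs^2, ys^2, xs * ys)
  cf <- stats::lsfit(X, zs, intercept = FALSE)$coefficients
  iface <- list(z0 = unname(cf[1]), gx = unname(cf[2]), gy = unname(cf[3]))
  if (fit == "quadratic") {
    iface$qxx <- unname(cf[4]); iface$qyy <- unname(cf[5])
    iface$qxy <- unname(cf[6])
  }
  attr(iface, "columns") <- data.frame(x = xs, y = ys, z = zs)
  iface
}

#' Two-pass dual speed-of-sound reconstruction
#'
#' The procedure behind the two-region model: reconstruct once with the
#' uniform water speed so superficial structures are sharp, segment the
#' water/tissue interface from that volume, then reconstruct again with
#' the two-region model split at the fitted surface. Optionally the
#' segment/reconstruct pair is iterated.
#'
#' @param sinogram band-passed sinogram (frame or matrix).
#' @param geometry an [ArrayGeometry-class].
#' @param grid a [VoxelGrid-class].
#' @param cWater,cTissue the two speeds of sound (m/s).
#' @param iterations number of segmentation passes (default 1).
#' @param ... passed to [segmentInterface()].
#' @return list with \code{volume} (dual-SOS [ReconVolume-class]),
#'   \code{interface}, and \code{singleSos} (the first-pass volume).
#' @export
dualSosReconstruct <- function(sinogram, geometry, grid = voxelGrid(),
                               cWater = 1400, cTissue = 1530,
                               iterations = 1L, ...) {
  single <- fbp(sinogram, geometry, uniformSos(cWater), grid)
  vol <- single
  iface <- NULL
  for (it in seq_len(iterations)) {
    iface <- segmentInterface(vol, ...)
    vol <- fbp(sinogram, geometry,
               twoRegionSos(cWater, cTissue, iface), grid)
  }
  list(volume = vol, interface = iface, singleSos = single)
}

#' Measure spatial resolution at a reconstructed point source
#'
#' Extracts 1-D profiles through the intensity peak along the lateral
#' (x, y) and axial (z) axes, fits a Gaussian to each, and reports the
#' full width at half maximum FWHM = 2 sqrt(2 ln 2) sigma in micrometres.
#' A non-convergent fit falls back to the direct half-maximum crossing
#' width and is flagged in the \code{"fallback"} attribute.
#'
#' @param volume a [ReconVolume-class] or [ImageVolume-class].
#' @param peakPositionMm optional length-3 position of the peak (mm);
#'   default: location of the absolute maximum.
#' @return named numeric c(lateralFwhmUm, axialFwhmUm); per-axis widths
#'   in attribute \code{"perAxisUm"}.
#' @export
measureResolution <- function(volume, peakPositionMm = NULL) {
  grid <- volume@grid
  v <- volume@values
  if (is.null(peakPositionMm)) {
    pk <- arrayInd(which.max(abs(v)), dim(v))
  } else {
    pk <- matrix(pmin(pmax(round((peakPositionMm - grid@originMm) /
                                   grid@voxelSizeMm + 0.5), 1), grid@dim),
                 1, 3)
  }
  if (any(pk == 1L) || any(pk == grid@dim))
    stop("peak lies on the grid boundary")
  widths <- numeric(3)
  fallback <- logical(3)
  for (a in 1:3) {
    idx <- as.list(pk[1, ])
    idx[[a]] <- seq_len(grid@dim[a])
    prof <- do.call(`[`, c(list(v), idx))
    prof <- prof * sign(v[pk])
    x <- (seq_along(prof) - 0.5) * grid@voxelSizeMm[a] + grid@originMm[a]
    w <- .gaussianFwhm(x, prof, x0 = x[pk[1, a]])
    widths[a] <- w$fwhmMm * 1000
    fallback[a] <- w$fallback
  }
  out <- c(lateralFwhmUm = mean(widths[1:2]), axialFwhmUm = widths[3])
  attr(out, "perAxisUm") <- stats::setNames(widths, c("x", "y", "z"))
  attr(out, "fallback") <- fallback
  out
}

# Gaussian FWHM of a 1-D profile; fit restricted to the central lobe
# (out to the first non-positive sample on each side of the peak).
.gaussianFwhm <- function(x, y, x0) {
  pk <- which.min(abs(x - x0))
  lo <- pk; while (lo > 1 && y[lo - 1] > 0) lo <- lo - 1
  hi <- pk; while (hi < length(y) && y[hi + 1] > 0) hi <- hi + 1
  xs <- x[lo:hi]; ys <- y[lo:hi]
  # moment-based starting width of the central lobe; the width start is
  # deliberately offset so the optimizer never begins exactly at a
  # stationary point
  sig0 <- sqrt(max(sum(ys * (xs - x[pk])^2) / sum(ys), diff(x[1:2])^2))
  fit <- NULL
  for (s0 in sig0 * c(1.5, 0.7, 1)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(ys ~ A * exp(-(xs - mu)^2 / (2 * sig^2)),
                        data = data.frame(xs = xs, ys = ys),
                        start = list(A = max(ys), mu = x[pk], sig = s0),
                        control = minpack.lm::nls.lm.control(maxiter =
                                                               200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (!is.null(fit)) {
    sig <- abs(stats::coef(fit)[["sig"]])
    return(list(fwhmMm = 2 * sqrt(2 * log(2)) * sig, fallback = FALSE))
  }
  # direct half-maximum crossing width
  half <- y[pk] / 2
  xl <- stats::approx(y[lo:pk], x[lo:pk], xout = half, ties = "ordered")$y
  xr <- stats::approx(rev(y[pk:hi]), rev(x[pk:hi]), xout = half,
                      ties = "ordered")$y
  list(fwhmMm = xr - xl, fallback = TRUE)
}
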