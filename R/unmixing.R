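#' Normalize a volume to laser pulse energy
#'
#' @param volume a [ReconVolume-class]/[ImageVolume-class] or plain array.
#' @param pulseEnergyMj pulse energy (> 0).
#' @return the volume with values divided by the pulse energy.
#' @export
normalizeEnergy <- function(volume, pulseEnergyMj) {
  if (!is.numeric(pulseEnergyMj) || pulseEnergyMj <= 0)
    stop("pulseEnergyMj must be positive")
  if (is(volume, "ImageVolume")) {
    volume@values <- volume@values / pulseEnergyMj
    volume
  } else volume / pulseEnergyMj
}

#' Exponential fluence correction
#'
#' Compensates the depth-dependent optical fluence decay: every voxel at
#' depth d below the water/tissue interface is multiplied by
#' exp(+muEff d); voxels on the water side are unchanged. With muEff = 0
#' this is the identity.
#'
#' @param volume a [ReconVolume-class] or [ImageVolume-class].
#' @param muEffMm effective attenuation coefficient (1/mm); default 0.6.
#' @param interface interface coefficient list (see
#'   [TwoRegionSOSModel-class]); depth is measured along +z from
#'   s(x, y).
#' @return the corrected volume.
#' @export
fluenceCorrect <- function(volume, muEffMm = 0.6,
                           interface = list(z0 = 0, gx = 0, gy = 0)) {
  if (muEffMm < 0) stop("muEffMm must be >= 0")
  grid <- volume@grid
  vox <- voxelCenters(grid)
  depth <- pmax(0, vox[, 3] - .surfaceHeight(interface, vox[, 1], vox[, 2]))
  volume@values <- array(as.numeric(volume@values) * exp(muEffMm * depth),
                         grid@dim)
  volume
}

#' Linear spectral unmixing into HbO and HbR
#'
#' Per-voxel least-squares solution of the linear system A = E c where A
#' stacks the (energy-normalized, fluence-corrected) reconstructions at
#' each wavelength and E holds the molar extinction coefficients. The
#' default non-negative solve clips via the active set of the
#' two-component problem; the unconstrained solution is available for
#' diagnostics. The per-voxel residual norm is returned for QC.
#'
#' @param volumesByWavelength named list of [ReconVolume-class] (or plain
#'   arrays), names = wavelengths in nm.
#' @param extinction extinction table as from [extinctionTable()];
#'   defaults to the shipped spectra at the supplied wavelengths.
#' @param nonneg constrain concentrations to be non-negative (default
#'   TRUE).
#' @return list with \code{hbo}, \code{hbr}, \code{residual} (all shaped
#'   like the inputs) and \code{extinction}.
#' @export
unmix <- function(volumesByWavelength, extinction = NULL, nonneg = TRUE) {
  wls <- as.numeric(names(volumesByWavelength))
  if (length(wls) < 2L) stop("need at least 2 wavelengths to unmix")
  if (is.null(extinction)) extinction <- extinctionTable(wls)
  if (!all(wls %in% extinction$wavelengthNm))
    stop("extinction table lacks wavelength(s): ",
         paste(setdiff(wls, extinction$wavelengthNm), collapse = ", "))
  E <- as.matrix(extinction[match(wls, extinction$wavelengthNm),
                            c("epsHbO", "epsHbR")])
  if (qr(E)$rank < 2L)
    stop("rank-deficient extinction system at wavelengths ",
         paste(wls, collapse = ", "))
  getv <- function(v) if (is(v, "ImageVolume")) v@values else v
  dims <- dim(getv(volumesByWavelength[[1]]))
  if (is.null(dims)) dims <- length(getv(volumesByWavelength[[1]]))
  Y <- do.call(rbind, lapply(volumesByWavelength,
                             function(v) as.numeric(getv(v))))
  # unconstrained normal-equations solve for all voxels at once
  C <- solve(crossprod(E), crossprod(E, Y))
  if (nonneg) {
    # two-component active set: refit with a clipped component fixed at 0
    for (j in 1:2) {
      neg <- C[j, ] < 0
      if (any(neg)) {
        other <- 3 - j
        e <- E[, other]
        C[j, neg] <- 0
        C[other, neg] <- pmax(0, colSums(e * Y[, neg, drop = FALSE]) /
                                   sum(e^2))
      }
    }
  }
  resid <- sqrt(colSums((Y - E %*% C)^2))
  shape <- function(x) array(x, dims)
  out <- list(hbo = shape(C[1, ]), hbr = shape(C[2, ]),
              residual = shape(resid), extinction = extinction)
  g <- volumesByWavelength[[1]]
  if (is(g, "ImageVolume")) {
    out$hbo <- new("ImageVolume", grid = g@grid, values = out$hbo)
    out$hbr <- new("ImageVolume", grid = g@grid, values = out$hbr)
  }
  out
}

#' Derive total hemoglobin and oxygen saturation
#'
#' HbT = HbO + HbR and sO2 = HbO / HbT, voxel-wise; sO2 is NA-masked
#' wherever HbT is at or below \code{hbtFloor}.
#'
#' @param hbo,hbr aligned arrays or [ImageVolume-class] objects.
#' @param hbtFloor sO2 mask floor (default 0).
#' @return list with \code{hbt} and \code{so2}.
#' @export
deriveComponents <- function(hbo, hbr, hbtFloor = 0) {
  getv <- function(v) if (is(v, "ImageVolume")) v@values else v
  o <- getv(hbo); r <- getv(hbr)
  if (!identical(dim(o), dim(r))) stop("hbo and hbr must be aligned")
  hbt <- o + r
  so2 <- ifelse(hbt > hbtFloor, o / hbt, NA_real_)
  if (is(hbo, "ImageVolume")) {
    hbt <- new("ImageVolume", grid = hbo@grid, values = array(hbt, dim(o)))
    so2 <- new("ImageVolume", grid = hbo@grid, values = array(so2, dim(o)))
  }
  list(hbt = hbt, so2 = so2)
}
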