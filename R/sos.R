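#' Uniform speed-of-sound model
#'
#' @param c speed of sound (m/s).
#' @return a [TwoRegionSOSModel-class] with equal speeds and no interface.
#' @export
uniformSos <- function(c = 1400) {
  new("TwoRegionSOSModel", cWater = c, cTissue = c, interface = list())
}

#' Two-region speed-of-sound model
#'
#' Heavy-water coupling medium on the detector side of the interface,
#' tissue on the far side.
#'
#' @param cWater water speed of sound (m/s), default 1400.
#' @param cTissue tissue speed of sound (m/s), default 1530.
#' @param interface surface coefficient list (see
#'   [TwoRegionSOSModel-class]); e.g. \code{list(z0 = -1, gx = 0, gy = 0)}
#'   for the plane z = -1 mm.
#' @return a [TwoRegionSOSModel-class].
#' @export
twoRegionSos <- function(cWater = 1400, cTissue = 1530,
                         interface = list(z0 = 0, gx = 0, gy = 0)) {
  new("TwoRegionSOSModel", cWater = cWater, cTissue = cTissue,
      interface = interface)
}

# Surface height s(x, y) of an interface coefficient list.
.surfaceHeight <- function(interface, x, y) {
  q <- function(nm) if (!is.null(interface[[nm]])) interface[[nm]] else 0
  interface$z0 + interface$gx * x + interface$gy * y +
    q("qxx") * x^2 + q("qyy") * y^2 + q("qxy") * x * y
}

#' Acoustic time of flight under a two-region model
#'
#' Straight-ray propagation time from voxel positions to a detector
#' element. Under the two-region model the segment is split at the
#' interface surface and each part travels at its region's speed:
#' t = L_water / c_water + L_tissue / c_tissue. With no interface (or equal
#' speeds) this degenerates to L / c.
#'
#' Refraction at the interface is ignored (delay correction along straight
#' rays); the interface polynomial is evaluated along the segment, so the
#' split is exact for plane and quadratic surfaces.
#'
#' @param voxelMm n x 3 matrix (or length-3 vector) of positions in mm.
#' @param elementMm length-3 element position in mm.
#' @param sosModel a [TwoRegionSOSModel-class].
#' @return numeric vector of propagation times in seconds.
#' @examples
#' timeOfFlight(c(0, 0, 0), c(0, 0, -40), uniformSos(1400)) # 28.571 us
#' @export
timeOfFlight <- function(voxelMm, elementMm, sosModel) {
  v <- matrix(voxelMm, ncol = 3)
  e <- as.numeric(elementMm)
  dx <- v[, 1] - e[1]; dy <- v[, 2] - e[2]; dz <- v[, 3] - e[3]
  dMm <- sqrt(dx^2 + dy^2 + dz^2)
  cw <- sosModel@cWater; ct <- sosModel@cTissue
  if (length(sosModel@interface) == 0L || cw == ct)
    return(dMm * 1e-3 / cw)
  f <- function(x, y, z) z - .surfaceHeight(sosModel@interface, x, y)
  # f(u) along the segment element -> voxel is quadratic in u for the
  # supported surfaces; fit it from three exact evaluations.
  f0 <- f(e[1], e[2], e[3])
  f1 <- f(v[, 1], v[, 2], v[, 3])
  fh <- f((e[1] + v[, 1]) / 2, (e[2] + v[, 2]) / 2, (e[3] + v[, 3]) / 2)
  A <- 2 * f0 - 4 * fh + 2 * f1
  B <- f1 - f0 - A
  C <- rep_len(f0, length(f1))
  waterFrac <- .negativeFraction(A, B, C)
  LwM <- dMm * waterFrac * 1e-3
  LtM <- dMm * (1 - waterFrac) * 1e-3
  LwM / cw + LtM / ct
}

# Fraction of u in [0, 1] where A u^2 + B u + C < 0 (vectorized).
.negativeFraction <- function(A, B, C) {
  n <- length(B)
  frac <- numeric(n)
  lin <- abs(A) < 1e-12
  # linear case: root at -C/B
  if (any(lin)) {
    Bl <- B[lin]; Cl <- C[lin]
    u <- ifelse(abs(Bl) < 1e-12, Inf, -Cl / Bl)
    startNeg <- Cl < 0
    f <- ifelse(u <= 0 | u >= 1,
                ifelse(startNeg | (Cl == 0 & Bl < 0), 1, 0),
                ifelse(startNeg, u, 1 - u))
    # constant segment entirely on one side
    const <- abs(Bl) < 1e-12
    f[const] <- as.numeric(Cl[const] < 0)
    frac[lin] <- f
  }
  if (any(!lin)) {
    Aq <- A[!lin]; Bq <- B[!lin]; Cq <- C[!lin]
    disc <- Bq^2 - 4 * Aq * Cq
    r1 <- r2 <- rep(NA_real_, length(Aq))
    has <- disc > 0
    sq <- sqrt(pmax(disc, 0))
    r1[has] <- ((-Bq - sq) / (2 * Aq))[has]
    r2[has] <- ((-Bq + sq) / (2 * Aq))[has]
    lo <- pmin(r1, r2); hi <- pmax(r1, r2)
    # measure of {u in [0,1]: f(u) < 0}: between the roots if A > 0,
    # outside them if A < 0
    inLo <- pmin(pmax(lo, 0), 1); inHi <- pmin(pmax(hi, 0), 1)
    between <- ifelse(has, inHi - inLo, 0)
    f <- ifelse(Aq > 0, between, 1 - between)
    f[!has & Aq > 0] <- 0   # always positive
    f[!has & Aq < 0] <- 1   # always negative
    frac[!lin] <- f
  }
  frac
}
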