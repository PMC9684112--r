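#' Construct a rigid transform
#'
#' Intrinsic z-y-x Euler rotation about \code{centerMm} followed by a
#' translation: p -> R (p - center) + center + t.
#'
#' @param anglesDeg rotations about z, y, x (degrees), applied in that
#'   order.
#' @param translationMm translation (mm).
#' @param centerMm rotation centre (mm).
#' @return a [RigidTransform-class].
#' @export
rigidTransform <- function(anglesDeg = c(0, 0, 0),
                           translationMm = c(0, 0, 0),
                           centerMm = c(0, 0, 0)) {
  new("RigidTransform", anglesDeg = as.numeric(anglesDeg),
      translationMm = as.numeric(translationMm),
      centerMm = as.numeric(centerMm))
}

.rotationMatrix <- function(anglesDeg) {
  a <- anglesDeg * pi / 180
  cz <- cos(a[1]); sz <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cx <- cos(a[3]); sx <- sin(a[3])
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Rz %*% Ry %*% Rx
}

# z-y-x Euler angles (degrees) of a rotation matrix R = Rz Ry Rx.
.eulerAngles <- function(R) {
  sy <- -R[3, 1]
  y <- asin(pmin(1, pmax(-1, sy)))
  if (abs(cos(y)) > 1e-9) {
    z <- atan2(R[2, 1], R[1, 1])
    x <- atan2(R[3, 2], R[3, 3])
  } else {  # gimbal lock
    z <- atan2(-R[1, 2], R[2, 2])
    x <- 0
  }
  c(z, y, x) * 180 / pi
}

#' Homogeneous 4 x 4 matrix of a rigid transform
#'
#' @param transform a [RigidTransform-class].
#' @return 4 x 4 affine matrix acting on column vectors in mm.
#' @export
transformMatrix <- function(transform) {
  R <- .rotationMatrix(transform@anglesDeg)
  ctr <- transform@centerMm
  t <- transform@translationMm + ctr - R %*% ctr
  rbind(cbind(R, t), c(0, 0, 0, 1))
}

# RigidTransform (about a given centre) equivalent to a 4 x 4 matrix.
.transformFromMatrix <- function(M, centerMm = c(0, 0, 0)) {
  R <- M[1:3, 1:3]
  t <- M[1:3, 4] - centerMm + R %*% centerMm
  rigidTransform(.eulerAngles(R), as.numeric(t), centerMm)
}

#' Apply a rigid transform to points
#'
#' @param transform a [RigidTransform-class].
#' @param pointsMm n x 3 matrix or length-3 vector (mm).
#' @return transformed points, same shape.
#' @export
transformPoints <- function(transform, pointsMm) {
  p <- matrix(pointsMm, ncol = 3)
  M <- transformMatrix(transform)
  out <- p %*% t(M[1:3, 1:3]) +
    matrix(M[1:3, 4], nrow(p), 3, byrow = TRUE)
  if (is.null(dim(pointsMm))) as.numeric(out) else out
}

#' @rdname composeTransforms
setMethod("composeTransforms", signature("RigidTransform", "RigidTransform"),
  function(t1, t2) {
    .transformFromMatrix(transformMatrix(t1) %*% transformMatrix(t2),
                         t1@centerMm)
  })

#' @rdname invertTransform
setMethod("invertTransform", "RigidTransform", function(x) {
  .transformFromMatrix(solve(transformMatrix(x)), x@centerMm)
})

#' Temporal mean volume of a 4-D series
#'
#' Collapses a [VolumeSeries-class] to its across-time mean, the usual
#' reference image for registering a functional series.
#'
#' @param series a [VolumeSeries-class].
#' @return an [ImageVolume-class].
#' @export
meanVolume <- function(series) {
  d <- dim(series@values)
  m <- rowMeans(matrix(series@values, prod(d[1:3]), d[4]))
  new("ImageVolume", grid = series@grid, values = array(m, d[1:3]))
}

# Trilinear sampling of a volume's values at physical points (mm);
# points outside the grid return NA.
.sampleVolume <- function(volume, pointsMm, interpolation = "trilinear") {
  grid <- volume@grid
  v <- volume@values
  d <- grid@dim
  u <- sweep(sweep(pointsMm, 2, grid@originMm, "-"), 2,
             grid@voxelSizeMm, "/") + 0.5
  if (interpolation == "nearest") {
    i <- round(u)
    ok <- i[, 1] >= 1 & i[, 1] <= d[1] & i[, 2] >= 1 & i[, 2] <= d[2] &
      i[, 3] >= 1 & i[, 3] <= d[3]
    out <- rep(NA_real_, nrow(u))
    out[ok] <- v[i[ok, , drop = FALSE]]
    return(out)
  }
  # snap near-integer coordinates so exact voxel-centre hits do not fall
  # out of range through floating-point jitter
  snap <- abs(u - round(u)) < 1e-9
  u[snap] <- round(u[snap])
  i0 <- floor(u)
  f <- u - i0
  # points landing exactly on the far-face voxel centres interpolate
  # from the cell below
  for (k in 1:3) {
    edge <- i0[, k] == d[k] & f[, k] == 0
    i0[edge, k] <- d[k] - 1L
    f[edge, k] <- 1
  }
  ok <- i0[, 1] >= 1 & i0[, 1] < d[1] & i0[, 2] >= 1 & i0[, 2] < d[2] &
    i0[, 3] >= 1 & i0[, 3] < d[3]
  out <- rep(NA_real_, nrow(u))
  if (!any(ok)) return(out)
  i0 <- i0[ok, , drop = FALSE]
  f <- f[ok, , drop = FALSE]
  idx <- function(dx, dy, dz)
    v[cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)]
  w <- function(dx, dy, dz)
    (dx * f[, 1] + (1 - dx) * (1 - f[, 1])) *
    (dy * f[, 2] + (1 - dy) * (1 - f[, 2])) *
    (dz * f[, 3] + (1 - dz) * (1 - f[, 3]))
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1)
    acc <- acc + w(dx, dy, dz) * idx(dx, dy, dz)
  out[ok] <- acc
  out
}

#' Reslice a volume under a rigid transform onto a target grid
#'
#' The transform maps moving-frame coordinates into the fixed frame; the
#' output volume on \code{targetGrid} (fixed frame) samples the moving
#' volume at the inverse-transformed grid points. Out-of-field voxels are
#' NA-masked.
#'
#' @param volume the moving [ImageVolume-class].
#' @param transform a [RigidTransform-class] (moving -> fixed).
#' @param targetGrid target [VoxelGrid-class]; default: the moving grid.
#' @param interpolation "trilinear" (default) or "nearest".
#' @return an [ImageVolume-class] on the target grid.
#' @export
reslice <- function(volume, transform = rigidTransform(),
                    targetGrid = NULL, interpolation = c("trilinear",
                                                         "nearest")) {
  interpolation <- match.arg(interpolation)
  if (is.null(targetGrid)) targetGrid <- volume@grid
  pts <- voxelCenters(targetGrid)
  src <- transformPoints(invertTransform(transform), pts)
  vals <- .sampleVolume(volume, src, interpolation)
  if (all(is.na(vals))) stop("empty overlap between volume and target grid")
  new("ImageVolume", grid = targetGrid,
      values = array(vals, targetGrid@dim))
}

# --- similarity metrics (higher is better) -------------------------------

.metricNcc <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 10) return(-Inf)
  a <- a[ok]; b <- b[ok]
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa == 0 || sb == 0) return(-Inf)
  abs(stats::cor(a, b))
}

# Normalized mutual information (Studholme), 32 x 32 bins on
# percentile-clipped intensities.
.metricNmi <- function(a, b, nBins = 32L) {
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 10) return(-Inf)
  a <- a[ok]; b <- b[ok]
  clip <- function(x) {
    q <- stats::quantile(x, c(0.01, 0.99), names = FALSE)
    if (q[1] == q[2]) return(NULL)
    pmin(pmax(x, q[1]), q[2])
  }
  a <- clip(a); b <- clip(b)
  if (is.null(a) || is.null(b)) return(-Inf)
  ia <- pmin(nBins, 1L + floor((a - min(a)) / (max(a) - min(a)) * nBins))
  ib <- pmin(nBins, 1L + floor((b - min(b)) / (max(b) - min(b)) * nBins))
  joint <- tabulate((ia - 1L) * nBins + ib, nbins = nBins * nBins)
  p <- joint / sum(joint)
  pj <- p[p > 0]
  pa <- rowSums(matrix(p, nBins, nBins, byrow = TRUE))
  pb <- colSums(matrix(p, nBins, nBins, byrow = TRUE))
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  hab <- -sum(pj * log(pj))
  (ha + hb) / hab
}

# Block-average downsampling of a volume by an integer factor.
.downsampleVolume <- function(volume, factor) {
  if (factor <= 1L) return(volume)
  d <- volume@grid@dim
  nd <- pmax(1L, d %/% factor)
  v <- volume@values[seq_len(nd[1] * factor), seq_len(nd[2] * factor),
                     seq_len(nd[3] * factor), drop = FALSE]
  a <- array(v, c(factor, nd[1], factor, nd[2], factor, nd[3]))
  vals <- apply(a, c(2, 4, 6), mean)
  grid <- new("VoxelGrid", originMm = volume@grid@originMm,
              voxelSizeMm = volume@grid@voxelSizeMm * factor, dim = nd)
  new("ImageVolume", grid = grid, values = vals)
}

#' Rigid registration of two volumes
#'
#' Finds the 6-DOF transform mapping the moving volume into the fixed
#' frame by maximizing an intensity similarity metric: normalized mutual
#' information for cross-modality pairs (default) or normalized
#' cross-correlation for same-modality pairs. Optimization is
#' multi-resolution (4x, 2x, 1x block-downsampling) with Nelder-Mead
#' descent per level and seeded random restarts.
#'
#' @param moving,fixed [ImageVolume-class] objects (any volume with a
#'   grid and values).
#' @param metric "nmi" (default) or "ncc".
#' @param init initial [RigidTransform-class] (moving -> fixed).
#' @param nStarts number of random restarts around the initial guess.
#' @param seed seed for the restarts.
#' @param maxit Nelder-Mead iteration cap per level.
#' @param levels downsampling factors of the pyramid.
#' @return the optimal [RigidTransform-class]; the metric value at the
#'   optimum is attached as attribute \code{"metricValue"}.
#' @export
registerRigid <- function(moving, fixed, metric = c("nmi", "ncc"),
                          init = NULL, nStarts = 3L, seed = 1L,
                          maxit = 400L, levels = c(4L, 2L, 1L),
                          maxPoints = 30000L) {
  metric <- match.arg(metric)
  mfun <- if (metric == "nmi") .metricNmi else .metricNcc
  ctr <- fixed@grid@originMm + fixed@grid@dim * fixed@grid@voxelSizeMm / 2
  if (is.null(init)) init <- rigidTransform(centerMm = ctr)
  par0 <- c(init@anglesDeg, init@translationMm)
  set.seed(seed)
  makeObjective <- function(mov, fix) {
    pts <- voxelCenters(fix@grid)
    ref <- as.numeric(fix@values)
    if (nrow(pts) > maxPoints) {  # deterministic stride subsample
      keep <- seq(1L, nrow(pts), length.out = maxPoints)
      pts <- pts[keep, , drop = FALSE]
      ref <- ref[keep]
    }
    function(par) {
      tr <- rigidTransform(par[1:3], par[4:6], ctr)
      src <- transformPoints(invertTransform(tr), pts)
      m <- mfun(.sampleVolume(mov, src), ref)
      if (!is.finite(m)) 1e6 else -m
    }
  }
  starts <- list(par0)
  for (s in seq_len(max(0L, nStarts - 1L)))
    starts[[s + 1L]] <- par0 + c(stats::rnorm(3, sd = 2),
                                 stats::rnorm(3, sd = 0.5))
  best <- NULL
  for (lev in levels) {
    obj <- makeObjective(.downsampleVolume(moving, lev),
                         .downsampleVolume(fixed, lev))
    cands <- if (is.null(best)) starts else list(best$par)
    res <- lapply(cands, function(p)
      stats::optim(p, obj, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = 1e-9,
                                  parscale = c(1, 1, 1, 0.5, 0.5, 0.5))))
    vals <- vapply(res, `[[`, numeric(1), "value")
    best <- res[[which.min(vals)]]
  }
  # restarted tight simplex at the finest level
  obj <- makeObjective(.downsampleVolume(moving, levels[length(levels)]),
                       .downsampleVolume(fixed, levels[length(levels)]))
  best <- stats::optim(best$par, obj, method = "Nelder-Mead",
                       control = list(maxit = maxit, reltol = 1e-12,
                                      parscale = c(0.2, 0.2, 0.2,
                                                   0.1, 0.1, 0.1)))
  if (best$value >= 1e6)
    stop("registration failed: no overlap or degenerate metric from any ",
         "start")
  out <- rigidTransform(best$par[1:3], best$par[4:6], ctr)
  attr(out, "metricValue") <- -best$value
  out
}
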