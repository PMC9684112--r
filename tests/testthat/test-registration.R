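test_that("rigid transforms form a group under compose and invert", {
  expect_equal(transformMatrix(invertTransform(rigidTransform())),
               diag(4))
  # composing pure translations adds the vectors
  t1 <- rigidTransform(translationMm = c(1, 2, 3))
  t2 <- rigidTransform(translationMm = c(-0.5, 1, 0))
  expect_equal(composeTransforms(t1, t2)@translationMm, c(0.5, 3, 3))
  # compose(t, invert(t)) is the identity for random transforms
  set.seed(4)
  for (i in 1:10) {
    tr <- rigidTransform(stats::runif(3, -40, 40),
                         stats::runif(3, -5, 5),
                         stats::runif(3, -2, 2))
    M <- transformMatrix(composeTransforms(tr, invertTransform(tr)))
    expect_lt(max(abs(M - diag(4))), 1e-9)
    # matrix round trip through the Euler parameterisation
    back <- oatpipe:::.transformFromMatrix(transformMatrix(tr),
                                           tr@centerMm)
    expect_lt(max(abs(transformMatrix(back) - transformMatrix(tr))),
              1e-9)
  }
})

test_that("reslicing shifts, masks, and round-trips as expected", {
  grid <- registrationGrid(c(24L, 24L, 12L), 0.4)
  vol <- featureVolume(grid)
  # identity transform, same grid: values unchanged
  same <- reslice(vol, rigidTransform(), grid)
  expect_equal(same@values, vol@values, tolerance = 1e-12)
  # translation by exactly one voxel: array shift with edge masking
  sh <- reslice(vol, rigidTransform(translationMm = c(0.4, 0, 0)), grid)
  expect_equal(sh@values[2:24, , ], vol@values[1:23, , ],
               tolerance = 1e-9)
  expect_true(all(is.na(sh@values[1, , ])))
  # reslice then reslice by the inverse recovers the original
  tr <- rigidTransform(c(4, -2, 3), c(0.3, -0.2, 0.1))
  fwd <- reslice(vol, tr, grid)
  fwd@values[is.na(fwd@values)] <- 0
  back <- reslice(fwd, invertTransform(tr), grid)
  ok <- !is.na(back@values)
  expect_gt(stats::cor(back@values[ok], vol@values[ok]), 0.99)
  # empty overlap errors
  expect_error(reslice(vol, rigidTransform(translationMm = c(100, 0, 0)),
                       grid), "overlap")
})

test_that("registration recovers identity and known transforms", {
  grid <- registrationGrid()
  fixed <- featureVolume(grid)
  # moving = fixed: identity within 0.05 mm / 0.1 degree
  tr0 <- registerRigid(fixed, fixed, metric = "ncc", seed = 1)
  expect_lt(max(abs(tr0@anglesDeg)), 0.1)
  expect_lt(max(abs(tr0@translationMm)), 0.05)
  # known shift + rotation recovered within 0.1 mm / 0.5 degree
  truth <- rigidTransform(c(5, 0, 0), c(0.5, 0.3, 0),
                          centerMm = c(0, 0, 0))
  moving <- featureVolume(grid, truth)
  rec <- registerRigid(moving, fixed, metric = "ncc", seed = 1)
  expect_lt(transformMatrixError(rec, truth), 0.1)
  expect_lt(max(abs(rec@anglesDeg - truth@anglesDeg)), 0.5)
  # metric at the optimum beats the misaligned identity
  obj <- attr(rec, "metricValue")
  idm <- oatpipe:::.metricNcc(as.numeric(moving@values),
                              as.numeric(fixed@values))
  expect_gte(obj, idm)
})

test_that("bounded random transforms are recovered across repetitions", {
  grid <- registrationGrid(c(32L, 32L, 16L), 0.35)
  fixed <- featureVolume(grid)
  set.seed(42)
  for (i in 1:10) {
    truth <- rigidTransform(stats::runif(3, -10, 10),
                            stats::runif(3, -2, 2), c(0, 0, 0))
    moving <- featureVolume(grid, truth)
    rec <- registerRigid(moving, fixed, metric = "ncc", seed = i,
                         maxit = 300L)
    expect_lt(max(abs(rec@anglesDeg - truth@anglesDeg)), 0.5)
    # compare the full maps, which folds translation and centre together
    expect_lt(transformMatrixError(rec, truth), 0.1)
  }
})

test_that("NMI registration aligns cross-modality volume pairs", {
  grid <- registrationGrid(c(32L, 32L, 16L), 0.35)
  ph <- hemoglobinPhantom(rbind(c(1, 0, 0.4), c(-1.2, 0.6, 0.6),
                                c(0.2, -1.4, 0.8)),
                          c(0.2, 0.25, 0.2), "vessel", so2 = 0.9)
  pts <- voxelCenters(grid)
  # T1-like contrast against an MRA-like contrast of the same scene
  fixed <- new("ImageVolume", grid = grid,
               values = array(oatpipe:::.sceneVessels(ph, pts) +
                                0.1 * oatpipe:::.sceneBrain(pts),
                              grid@dim))
  truth <- rigidTransform(c(-4, 2, 0), c(-0.4, 0.25, 0.2), c(0, 0, 0))
  mpts <- transformPoints(truth, pts)
  moving <- new("ImageVolume", grid = grid,
                values = array(oatpipe:::.sceneBrain(mpts) +
                                 0.05 * oatpipe:::.sceneVessels(ph, mpts),
                               grid@dim))
  rec <- registerRigid(moving, fixed, metric = "nmi", seed = 1)
  expect_lt(transformMatrixError(rec, truth), 0.3)
})

test_that("the registration chain maps BOLD to the OAT frame", {
  chain <- cachedFixture("coregChain", {
    ph <- hemoglobinPhantom(rbind(c(1, 0, 0.4), c(-1.2, 0.6, 0.6),
                                  c(0.2, -1.4, 0.8)),
                            c(0.2, 0.25, 0.2), "vessel", so2 = 0.9)
    grids <- list(
      mra = voxelGrid(c(-6, -6, -2), c(0.15, 0.15, 0.3),
                      c(80L, 80L, 14L)),
      t1Transverse = voxelGrid(c(-6, -6, -2), c(0.2, 0.2, 0.3),
                               c(60L, 60L, 14L)),
      t1Coronal = voxelGrid(c(-6, -4, -2.5), c(0.2, 0.2, 0.5),
                            c(60L, 40L, 10L)),
      bold = voxelGrid(c(-6, -4, -2.5), c(0.3, 0.3, 0.5),
                       c(40L, 27L, 10L)))
    trs <- list(mra = rigidTransform(c(2, -1, 1), c(0.5, -0.3, 0.2)),
                t1Transverse = rigidTransform(c(-1.5, 0.5, -1),
                                              c(-0.4, 0.2, 0.1)),
                t1Coronal = rigidTransform(c(1, 1, -0.5),
                                           c(0.2, 0.4, -0.2)),
                bold = rigidTransform(c(-0.5, -1, 0.8),
                                      c(-0.3, -0.2, 0.3)))
    hemo <- simulateParadigmHemodynamics(seed = 3)
    mri <- simulateMriVolumes(ph, grids, trs, hemo = hemo, seed = 4)
    tMra <- registerRigid(mri$mra, mri$oatReference, metric = "ncc",
                          seed = 1)
    tT1t <- registerRigid(mri$t1Transverse, mri$mra, metric = "nmi",
                          seed = 1)
    tT1c <- registerRigid(mri$t1Coronal, mri$t1Transverse,
                          metric = "ncc", seed = 1)
    tBold <- registerRigid(meanVolume(mri$bold), mri$t1Coronal,
                           metric = "ncc", seed = 1)
    est <- composeTransforms(tMra, composeTransforms(
      tT1t, composeTransforms(tT1c, tBold)))
    list(est = est, truthBold = trs$bold, mri = mri)
  })
  vOat <- intensityCentroid(chain$mri$oatReference)
  xBold <- transformPoints(invertTransform(chain$truthBold), vOat)
  err <- abs(transformPoints(chain$est, xBold) - vOat)
  # within one BOLD voxel per axis (0.3 x 0.3 x 0.5 mm test grids)
  expect_true(all(err <= c(0.3, 0.3, 0.5)))
})
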