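test_that("hemispherical array satisfies the geometry invariants", {
  g <- buildHemisphericalArray()
  p <- elementPositions(g)
  expect_equal(nrow(p), 384L)
  r <- sqrt(rowSums(p^2))
  expect_true(all(abs(r - 40) < 1e-4))  # on the sphere within 0.1 um
  theta <- acos(-p[, 3] / r) * 180 / pi
  expect_true(all(theta <= 65 + 1e-6))
  # brute-force pairwise spacing scan of the lattice
  D <- as.matrix(dist(p)); diag(D) <- Inf
  expect_gt(min(D), 2)
  # deterministic for fixed arguments
  expect_identical(p, elementPositions(buildHemisphericalArray()))
})

test_that("degenerate and invalid array configurations are handled", {
  g1 <- buildHemisphericalArray(1L)
  expect_equal(as.numeric(elementPositions(g1)), c(0, 0, -40))
  expect_error(buildHemisphericalArray(radiusMm = -1), "radius")
  expect_error(buildHemisphericalArray(samplingRate = 0), "samplingRate")
  expect_error(buildHemisphericalArray(apertureDeg = 200), "aperture")
})

test_that("gas mixture arithmetic reproduces the protocol FiO2 values", {
  expect_equal(fio2OfMixture(200, 800, 0.20), 0.36)
  expect_equal(fio2OfMixture(0, 500, 0.20), 0.20)
  expect_equal(fio2OfMixture(500, 0, 0.20), 1.00)
  expect_error(fio2OfMixture(0, 0), "positive")
  expect_error(fio2OfMixture(-1, 10), "non-negative")
})

test_that("the stimulation paradigm totals 15 minutes with valid FiO2", {
  par <- stimulusParadigm()
  expect_equal(totalDuration(par), 900)
  f <- fio2Trace(par)
  expect_length(f, 900)
  expect_equal(f[1], 0.36)
  expect_equal(f[181], 0.20)   # first normoxia segment
  expect_equal(f[301], 1.00)   # first hyperoxia segment
  expect_true(all(f > 0 & f <= 1))
  expect_error(stimulusParadigm(fio2Normoxia = 0), "FiO2")
})

test_that("paradigm hemodynamics conserve HbT and order compartments", {
  h <- simulateParadigmHemodynamics(seed = 1, noiseSd = 0.002)
  for (cp in unique(h$compartment)) {
    sub <- h[h$compartment == cp, ]
    expect_equal(sub$hbo + sub$hbr, sub$hbt)              # exact by design
    expect_equal(diff(range(sub$hbt)), 0)
  }
  # vessel modulation exceeds parenchymal modulation
  amp <- function(cp) {
    sub <- h[h$compartment == cp, ]
    max(abs(sub$hbo / mean(sub$hbo[1:180]) - 1))
  }
  expect_gt(amp("vessel"), amp("parenchyma"))
  # hyperoxia raises HbO and sO2, lowers HbR relative to baseline
  v <- h[h$compartment == "vessel", ]
  hyper <- v$timeS >= 340 & v$timeS < 420  # deep into first hyperoxia
  base <- v$timeS < 180
  expect_gt(mean(v$hbo[hyper]), mean(v$hbo[base]))
  expect_lt(mean(v$hbr[hyper]), mean(v$hbr[base]))
  # zero gain leaves the traces flat
  h0 <- simulateParadigmHemodynamics(
    compartments = data.frame(label = "vessel", so2Baseline = 0.8,
                              gain = 0, hbt = 1), seed = 1)
  expect_equal(diff(range(h0$hbo)), 0)
  expect_error(simulateParadigmHemodynamics(
    compartments = data.frame(label = "vessel", so2Baseline = 0.8,
                              gain = -1, hbt = 1)), "gains")
  # identical seeds are bit-identical
  expect_identical(simulateParadigmHemodynamics(seed = 7, noiseSd = 0.01),
                   simulateParadigmHemodynamics(seed = 7, noiseSd = 0.01))
})

test_that("forward model places arrivals at the time-of-flight sample", {
  g <- buildHemisphericalArray(nSamples = 1400L, delayS = 0)
  ph <- phantom(data.frame(x = 0, y = 0, z = 0, radiusMm = 0.02,
                           compartment = "vessel"),
                absorption = matrix(1, 1, 1), wavelengthsNm = 800)
  fr <- simulateSinogram(ph, g, uniformSos(1400), 800)
  # oracle: arrival sample = 40 mm / 1400 m/s * 40 Msps ~ 1143 after
  # emission (1-based indexing and the band-limited wavelet shift the
  # peak by about one sample)
  for (ch in c(1L, 100L, 384L))
    expect_lt(abs(which.max(abs(fr@data[ch, ])) - 1144), 3)
})

test_that("empty phantoms and truncated arrivals behave as specified", {
  g <- smallGeometry()
  fr <- simulateSinogram(phantom(), g, uniformSos(1400), 800)
  expect_true(all(fr@data == 0))
  # absorber outside the short recorded window warns and truncates
  far <- phantom(data.frame(x = 0, y = 0, z = 30, radiusMm = 0.1,
                            compartment = "vessel"),
                 absorption = matrix(1, 1, 1), wavelengthsNm = 800)
  expect_warning(simulateSinogram(far, smallGeometry(nSamples = 16L),
                                  uniformSos(1400), 800), "truncated")
  # same seed, same noise
  p1 <- simulateSinogram(smallPhantom(), g, uniformSos(1400), 700,
                         noiseSd = 0.1, seed = 9)
  p2 <- simulateSinogram(smallPhantom(), g, uniformSos(1400), 700,
                         noiseSd = 0.1, seed = 9)
  expect_identical(p1@data, p2@data)
})

test_that("mirror-symmetric phantoms give permutation-symmetric sinograms", {
  # explicit mirror-closed element set: pairs (x,y,z) and (-x,y,z)
  base <- buildHemisphericalArray(6L)@positions
  pos <- rbind(base, cbind(-base[, 1], base[, 2], base[, 3]))
  g <- arrayGeometry(pos, nSamples = 256L)
  ph <- phantom(data.frame(x = c(0.6, -0.6), y = c(0.2, 0.2),
                           z = c(0.3, 0.3), radiusMm = 0.05,
                           compartment = "vessel"),
                absorption = matrix(1, 2, 1), wavelengthsNm = 800)
  fr <- simulateSinogram(ph, g, uniformSos(1400), 800)
  perm <- c(7:12, 1:6)  # the x-mirror channel permutation
  expect_equal(fr@data, fr@data[perm, ], tolerance = 1e-10)
})

test_that("corruption injection marks exactly the overlapped frames", {
  st <- smallStream(durationS = 30, noiseSd = 0, seed = 1)
  tm <- acquisitionTiming(durationS = 30)
  inj <- injectMriCorruption(st, tm, burstAmplitude = 1, seed = 3)
  # brute-force interval-overlap oracle over the slice-event comb
  ev <- as.vector(outer((0:10) * 0.995 / 11, (0:ceiling(30 / 0.995)) * 0.995,
                        "+"))
  oracle <- vapply(seq_len(nFrames(st)), function(f) {
    t0 <- st@timestampS[f]
    any(ev >= t0 & ev < t0 + 1 / 50)
  }, logical(1))
  expect_identical(inj$mask, oracle)
  expect_equal(mean(inj$mask), 11 / 0.995 / 50, tolerance = 0.02)
  # zero amplitude: data untouched, mask still set
  inj0 <- injectMriCorruption(st, tm, burstAmplitude = 0, seed = 3)
  expect_identical(inj0$stream@data, st@data)
  expect_identical(inj0$mask, inj$mask)
  # a single explicit event corrupts exactly the frame containing it
  inj1 <- injectMriCorruption(st, tm, burstAmplitude = 1, seed = 3,
                              eventTimesS = 10.00)
  expect_identical(which(inj1$mask), which(st@timestampS <= 10 &
                                             st@timestampS + 1 / 50 > 10))
  expect_error(injectMriCorruption(st, tm, jitterSd = -1), "jitterSd")
})

test_that("full-paradigm frame accounting is exact", {
  g <- smallGeometry(4L, 8L)
  st <- simulateStream(phantom(), g, acquisitionTiming(durationS = 900),
                       seed = 1)
  expect_equal(nFrames(st), 45000L)
  expect_true(all(table(wavelengths(st)) == 9000L))
})

test_that("simulated MRI volumes encode their rigid transforms", {
  ph <- hemoglobinPhantom(rbind(c(1, 0, 0.4)), 0.2, "vessel", 0.9)
  grids <- list(
    mra = voxelGrid(c(-4, -4, -1.5), c(0.2, 0.2, 0.3), c(40L, 40L, 10L)),
    t1Transverse = voxelGrid(c(-4, -4, -1.5), c(0.25, 0.25, 0.3),
                             c(32L, 32L, 10L)),
    t1Coronal = voxelGrid(c(-4, -3, -2), c(0.25, 0.25, 0.5),
                          c(32L, 24L, 8L)),
    bold = voxelGrid(c(-4, -3, -2), c(0.3, 0.3, 0.5), c(27L, 20L, 8L)))
  hemo <- simulateParadigmHemodynamics(seed = 2)
  # identity transforms: vessel centroids coincide across frames
  mri0 <- simulateMriVolumes(ph, grids, hemo = hemo, seed = 5,
                             noiseSd = 0)
  c0 <- intensityCentroid(mri0$mra, 0.7)
  expect_lt(max(abs(c0 - c(1, 0, 0.4))), max(grids$mra@voxelSizeMm))
  # pure translation shifts the centroid by the inverse offset
  mriT <- simulateMriVolumes(
    ph, grids, transforms = list(mra = rigidTransform(translationMm =
                                                        c(0.5, 0, 0))),
    hemo = hemo, seed = 5, noiseSd = 0)
  cT <- intensityCentroid(mriT$mra, 0.7)
  expect_equal(cT - c0, c(-0.5, 0, 0), tolerance = 0.05)
  # BOLD ROI mean tracks the parenchyma HbO trace
  tc <- apply(mri0$bold@values, 4, mean)
  par <- hemo[hemo$compartment == "parenchyma", ]
  expect_gt(cor(tc, par$hbo), 0.5)
})
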