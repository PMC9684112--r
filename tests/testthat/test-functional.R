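test_that("ROI time courses average the cube voxels", {
  grid <- voxelGrid(c(-1, -1, -1), 0.2, c(10L, 10L, 10L))
  nT <- 5L
  ser <- new("VolumeSeries", grid = grid,
             values = array(3, c(grid@dim, nT)), timeS = 0:4)
  expect_equal(roiTimecourse(ser, roiSpec(c(0, 0, 0), 0.4)), rep(3, nT))
  # one-voxel ROI returns that voxel's series
  arr <- array(stats::rnorm(prod(grid@dim) * nT), c(grid@dim, nT))
  ser2 <- new("VolumeSeries", grid = grid, values = arr, timeS = 0:4)
  one <- roiTimecourse(ser2, roiSpec(c(-0.9, -0.9, -0.9), 0.15))
  expect_equal(one, arr[1, 1, 1, ])
  # two half-value regions split by the cube average to their mean
  half <- array(2, c(grid@dim, 1L))
  half[1:5, , , ] <- 4
  ser3 <- new("VolumeSeries", grid = grid, values = half, timeS = 0)
  expect_equal(roiTimecourse(ser3, roiSpec(c(0, 0, 0), 0.8)), 3)
  expect_error(roiTimecourse(ser, roiSpec(c(9, 9, 9), 0.4)), "outside")
})

test_that("fractional change normalizes to the baseline window", {
  expect_equal(fractionalChange(rep(7, 300)), rep(0, 300))
  s <- c(rep(10, 180), rep(20, 120))
  expect_equal(fractionalChange(s)[181], 1)
  expect_equal(fractionalChange(c(rep(10, 180), 10.5))[181], 0.05)
  expect_error(fractionalChange(rep(0, 300)), "zero")
  expect_error(fractionalChange(rep(1, 10)), "baseline")
})

test_that("zero-phase smoothing meets its frequency response", {
  const <- rep(3.3, 100)
  expect_equal(smoothTimecourse(const), const, tolerance = 1e-3)
  # sinusoid at the half-power frequency comes out at 1/sqrt(2)
  t <- 0:899
  x <- sin(2 * pi * 0.075 * t)  # normalized 0.15 on the Nyquist axis
  y <- smoothTimecourse(x)
  sel <- 101:800
  fit <- stats::lm(y[sel] ~ sin(2 * pi * 0.075 * t[sel]) +
                     cos(2 * pi * 0.075 * t[sel]) - 1)
  expect_equal(sqrt(sum(stats::coef(fit)^2)), 1 / sqrt(2),
               tolerance = 0.01)
  # white noise loses variance
  set.seed(8)
  w <- stats::rnorm(500)
  expect_lt(stats::var(smoothTimecourse(w)), stats::var(w))
  expect_error(smoothTimecourse(stats::rnorm(5)), "short")
})

test_that("per-cycle response amplitudes isolate the stimulation windows", {
  par <- stimulusParadigm()
  expect_equal(responseAmplitudes(rep(0, 900), par), rep(0, 3))
  # a step of +0.1 confined to cycle 2
  s <- rep(0, 900)
  s[421:660] <- 0.1  # cycle 2 spans 420-660 s
  expect_equal(responseAmplitudes(s, par), c(0, 0.1, 0))
  expect_error(responseAmplitudes(rep(0, 100), par), "beyond")
  # amplitude extraction is stable under smoothing for step-like
  # responses with the generator's first-order transition kinetics
  target <- rep(0, 900)
  for (w in seq_len(3))
    target[(180 + (w - 1) * 240 + 120):(180 + w * 240)] <- 0.2
  dss <- Reduce(function(prev, k) prev + (1 - exp(-1 / 10)) *
                  (target[k] - prev), 2:900, accumulate = TRUE,
                init = 0)
  ampRaw <- responseAmplitudes(dss, par)
  ampSm <- responseAmplitudes(smoothTimecourse(dss), par)
  expect_true(all(abs(ampSm - ampRaw) / ampRaw < 0.05))
})

test_that("component comparison implements the two-sample t-test", {
  same <- c(1, 2, 3)
  res <- compareComponents(same, same)
  expect_equal(res$t, 0, tolerance = 1e-12)
  expect_equal(res$p, 1)
  expect_false(res$significant)
  # N(0,1) vs N(5,1) with n = 9 per group is significant at alpha 0.05
  set.seed(10)
  a <- stats::rnorm(9); b <- stats::rnorm(9, mean = 5)
  res2 <- compareComponents(a, b)
  expect_true(res2$significant)
  expect_equal(res2$p, stats::t.test(a, b, var.equal = TRUE)$p.value)
  # Welch variant matches stats::t.test
  res3 <- compareComponents(a, b, welch = TRUE)
  expect_equal(res3$p, stats::t.test(a, b)$p.value)
  # degenerate equal-mean zero-variance groups: p = 1 by convention
  res4 <- compareComponents(c(2, 2, 2), c(2, 2, 2))
  expect_equal(res4$p, 1)
  expect_false(res4$significant)
  expect_error(compareComponents(1, c(1, 2)), "n >= 2")
})

test_that("dS/S after smoothing is invariant to affine signal rescaling", {
  set.seed(12)
  s <- 10 + cumsum(stats::rnorm(400, sd = 0.05))
  f1 <- smoothTimecourse(fractionalChange(s))
  f2 <- smoothTimecourse(fractionalChange(5 * s))
  expect_equal(f1, f2, tolerance = 1e-10)
})

test_that("the synthetic paradigm reproduces the expected sign pattern", {
  # direct generator-to-analysis path at the full 15-min paradigm
  par <- stimulusParadigm()
  h <- simulateParadigmHemodynamics(par, seed = 21, noiseSd = 0.002)
  traces <- list()
  for (cp in c("vessel", "parenchyma")) {
    sub <- h[h$compartment == cp, ]
    traces[[cp]] <- list(
      hbo = fractionalChange(sub$hbo), hbr = fractionalChange(sub$hbr),
      hbt = fractionalChange(sub$hbt + stats::rnorm(nrow(sub), sd = 1e-6)),
      so2 = fractionalChange(sub$so2))
  }
  hyper <- 341:420  # deep in the first hyperoxia segment
  v <- traces$vessel
  expect_gt(mean(v$hbo[hyper]), 0)
  expect_gt(mean(v$so2[hyper]), 0)
  expect_lt(mean(v$hbr[hyper]), 0)
  # HbT amplitudes are the smallest of all components
  amp <- vapply(v, function(x) max(responseAmplitudes(x, par)),
                numeric(1))
  expect_true(all(amp["hbt"] < amp[c("hbo", "hbr", "so2")]))
  # vessel responses exceed parenchymal responses component-wise
  ampP <- vapply(traces$parenchyma,
                 function(x) max(responseAmplitudes(x, par)), numeric(1))
  for (cmp in c("hbo", "hbr", "so2"))
    expect_gt(amp[[cmp]], ampP[[cmp]])
})
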