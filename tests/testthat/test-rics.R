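test_that("FFT autocorrelation equals the direct oracle", {
  set.seed(10)
  for (dims in list(c(8, 8), c(5, 9), c(16, 16))) {
    f <- matrix(runif(prod(dims), 0.5, 2), dims[1], dims[2])
    mr <- min(3, dims[1] - 1); mc <- min(4, dims[2] - 1)
    expect_lt(max(abs(spatialAutocorrelation(f, mc, mr) -
                        autocorrOracle(f, mr, mc))), 1e-10)
  }
})

test_that("zero-shift autocorrelation equals variance over squared mean", {
  f <- matrix(0, 4, 4); f[2, 3] <- 16
  G <- spatialAutocorrelation(f, 2, 2)
  expect_equal(G["0", "0"], 15)          # <I^2>/<I>^2 - 1 with <I> = 1
  expect_equal(max(abs(spatialAutocorrelation(matrix(5, 8, 8), 3, 3))), 0)
  expect_error(spatialAutocorrelation(matrix(0, 4, 4), 2, 2), "positive")
})

test_that("ricsAverage averages per-frame surfaces element-wise", {
  set.seed(11)
  mt <- testMeta(12, 12)
  f1 <- matrix(runif(144, 1, 3), 12, 12)
  f2 <- matrix(runif(144, 1, 3), 12, 12)
  st <- imageStack(array(c(f1, f2), c(12, 12, 2))[c(1, 2), , , drop = FALSE], mt)
  # build explicitly: frame 1 = f1, frame 2 = f2
  arr <- array(0, c(2, 12, 12)); arr[1, , ] <- f1; arr[2, , ] <- f2
  st <- imageStack(arr, mt)
  got <- surface(ricsAverage(st, maxShiftCol = 4, maxShiftRow = 4, highpass = 0))
  want <- (spatialAutocorrelation(f1, 4, 4) + spatialAutocorrelation(f2, 4, 4)) / 2
  expect_equal(got, want, tolerance = 1e-12)
  # identical frames: average equals the single-frame surface
  arr2 <- array(rep(f1, each = 10), c(10, 12, 12))
  got2 <- surface(ricsAverage(imageStack(arr2, mt), maxShiftCol = 4,
                              maxShiftRow = 4, highpass = 0))
  expect_equal(got2, spatialAutocorrelation(f1, 4, 4), tolerance = 1e-12)
})

test_that("RICS model surface has the documented zero-shift structure", {
  mt <- ricsAcquisition()
  for (D in c(0.5, 10, 80)) {
    S <- ricsModelSurface(D, N = 4, b = 0.02, mt)
    expect_equal(S["0", "0"], 0.3536 / 4 + 0.02)  # S(0,0)=1, G(0,0)=gamma/N+b
    expect_true(all(S["0", ] <= S["0", "0"] + 1e-15))
  }
})

test_that("fitRICS inverts a noise-free model surface", {
  mt <- ricsAcquisition()
  S <- ricsModelSurface(D = 10, N = 5, b = 0, mt)
  corr <- new("RICSCorrelation", surface = S, nFramesAveraged = 1L, meta = mt)
  fit <- fitRICS(corr)
  expect_lt(abs(fit@D / 10 - 1), 0.01)
  expect_lt(abs(fit@N / 5 - 1), 0.01)
  expect_gt(fit@fitR2, 0.999)
})

test_that("RICS D recovery is invariant to intensity rescaling", {
  mt <- ricsAcquisition()
  cfg <- sceneConfig(nParticles = 100, brightness = 5, width = 128, height = 128,
                     nFrames = 60, meta = mt, poissonNoise = FALSE, seed = 21L)
  st <- simulateStack(diffusionModel(10), cfg, sampling = "line")
  f1 <- fitRICS(ricsAverage(st, highpass = 0))
  st2 <- imageStack(frames(st) * 3.7, mt)
  f2 <- fitRICS(ricsAverage(st2, highpass = 0))
  expect_equal(f1@D, f2@D, tolerance = 1e-6)
  expect_equal(f1@N, f2@N, tolerance = 1e-6)
  # and the recovered D is close to the simulated truth
  expect_lt(abs(f1@D / 10 - 1), 0.25)
})

test_that("diffusion broadens the correlation beyond the static PSF", {
  mt <- ricsAcquisition()
  mk <- function(D) {
    cfg <- sceneConfig(nParticles = 100, brightness = 5, width = 128,
                       height = 128, nFrames = 30, meta = mt,
                       poissonNoise = FALSE, seed = 22L)
    model <- if (D > 0) diffusionModel(D) else boundModel(Inf)
    surface(ricsAverage(simulateStack(model, cfg, "line"), highpass = 0))
  }
  Sd <- mk(5); S0 <- mk(0)
  # normalized fast-axis profile decays more slowly for the diffusing scene
  profD <- Sd["0", as.character(0:10)] / Sd["0", "1"]
  prof0 <- S0["0", as.character(0:10)] / S0["0", "1"]
  expect_true(all(profD[4:11] > prof0[4:11]))
  expect_true(all(diff(profD[2:11]) < 0))   # monotone decay away from zero
})
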