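test_that("STICS correlation equals the quadruple-loop oracle", {
  set.seed(30)
  mt <- testMeta(8, 8)
  arr <- array(runif(12 * 64, 0.5, 2), c(12, 8, 8))
  fl <- removeTimeAverage(imageStack(arr, mt))
  for (lag in c(1L, 2L, 5L)) {
    got <- surface(sticsCorrelate(fl, lags = lag, maxShift = 3L))
    expect_lt(max(abs(got - sticsOracle(fl, lag, 3L))), 1e-10)
  }
})

test_that("static stacks correlate to zero at every lag", {
  mt <- testMeta(8, 8)
  img <- matrix(runif(64, 1, 2), 8, 8)
  fl <- removeTimeAverage(imageStack(array(rep(img, each = 10), c(10, 8, 8)), mt))
  for (lag in 1:3) {
    expect_equal(max(abs(surface(sticsCorrelate(fl, lags = lag, maxShift = 3L)))), 0)
  }
  expect_error(sticsCorrelate(fl, lags = 10L, maxShift = 3L), "lag")
  expect_error(sticsCorrelate(fl, lags = 1L, maxShift = 5L), "maxShift")
})

test_that("mixture fit recovers generated isotropic components", {
  S <- mixtureSurface(a1 = 0.01, s1 = 2, eps = 2e-4, noiseSD = 1e-5, seed = 31)
  f <- fitMixture(S)
  expect_equal(classification(f), "isotropic")
  iso <- components(f, "isotropic")
  expect_lt(abs(iso@amplitude / 0.01 - 1), 0.05)
  expect_lt(abs(iso@sigmaMajor / 2 - 1), 0.05)
  expect_gt(f@r2, 0.99)
  expect_true(all(is.finite(f@stderr)))
})

test_that("mixture fit recovers an offset anisotropic component", {
  S <- mixtureSurface(a1 = 0.01, s1 = 2, eps = 0, a2 = 0.008, mux = 2,
                      muy = -1, sM = 3, sm = 1, th = 30 * pi / 180,
                      noiseSD = 2e-5, seed = 32)
  f <- fitMixture(S)
  expect_equal(classification(f), "isotropic+anisotropic")
  an <- components(f, "anisotropic")
  expect_lt(angularErrDeg(an@theta, 30 * pi / 180), 5)
  expect_lt(abs(an@sigmaMajor / an@sigmaMinor - 3), 0.3)
  expect_equal(an@center, c(2, -1), tolerance = 0.1)
})

test_that("structureless surfaces are classified as noise", {
  S <- mixtureSurface(a1 = 0, s1 = 1, eps = 0, noiseSD = 1e-4, seed = 33)
  f <- fitMixture(S)
  expect_equal(classification(f), "noise")
  expect_lte(f@r2, 0.1)
})

test_that("likelihood-ratio model selection follows the chi-squared tail", {
  expect_equal(selectModel(1, 1, 289), 1)              # nested boundary
  expect_equal(selectModel(1, 1.2, 289), 1)            # numerics guard
  p <- selectModel(1.5, 1.0, 289)
  expect_equal(p, pchisq(289 * log(1.5), 6, lower.tail = FALSE))
  expect_lt(p, 1e-20)
  expect_error(selectModel(1, 0.9, 5), "too few")
})

test_that("spurious anisotropy is rare on pure isotropic surfaces", {
  set.seed(34)
  acc <- 0; nrep <- 60
  for (i in seq_len(nrep)) {
    S <- mixtureSurface(a1 = 0.01, s1 = 2, eps = 0, noiseSD = 4e-4)
    if (fitMixture(S)@lrtP < 0.05) acc <- acc + 1
  }
  expect_lte(acc / nrep, 0.10 + 0.05)  # nominal 5%, small-sample slack
})

test_that("micsMap yields one fit per window and lag in long format", {
  mt <- micsAcquisition(width = 64, height = 32)
  cfg <- sceneConfig(nParticles = 300, brightness = 1, width = 64, height = 32,
                     nFrames = 120, meta = mt, poissonNoise = TRUE, seed = 35L)
  st <- simulateStack(diffusionModel(0.05), cfg, "frame")
  km <- micsMap(st, windowSize = 32, step = 16, maxLag = 5, maxShift = 8)
  expect_equal(nrow(km@windows), 3L)
  expect_equal(length(km@lags), 5L)
  df <- as.data.frame(km)
  expect_equal(nrow(df), 15L)
  expect_true(all(c("window_row", "window_col", "lag_frames", "lag_s",
                    "classification", "a1", "sigma_iso", "a2", "theta",
                    "epsilon", "r2", "lrt_p") %in% names(df)))
  expect_equal(df$lag_s, df$lag_frames * mt@frameInterval)
})

test_that("component summaries convert widths to FWHM in micrometres", {
  mt <- micsAcquisition()
  iso <- new("GaussianComponent", amplitude = 0.01, center = c(0, 0),
             sigmaMajor = 2, sigmaMinor = 2, theta = 0, isIsotropic = TRUE)
  f <- new("MixtureFit", components = list(iso), epsilon = 0, r2 = 0.9,
           lrtP = 0.5, classification = "isotropic", stderr = NA_real_,
           sse = 0, lagFrames = 1L, lagSeconds = 0.0496, converged = TRUE)
  rec <- summarizeComponent(f, mt)
  expect_equal(rec$fwhm_major_um, 2 * sqrt(2 * log(2)) * 2 * 0.1,
               tolerance = 1e-12)        # 0.4710 um
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$type, "isotropic")
  # noise classifications produce an empty record
  fn <- new("MixtureFit", components = list(), epsilon = 0, r2 = 0.05,
            lrtP = 1, classification = "noise", stderr = NA_real_,
            sse = 0, lagFrames = 1L, lagSeconds = 0.0496, converged = TRUE)
  expect_equal(nrow(summarizeComponent(fn, mt)), 0L)
})

test_that("amplitudes below the reporting gate drop the component", {
  S <- mixtureSurface(a1 = 0.01, s1 = 2, eps = 0, a2 = 5e-5, mux = 3,
                      muy = 0, sM = 2, sm = 1, th = 0, noiseSD = 1e-6,
                      seed = 36)
  f <- fitMixture(S)
  # whatever the LRT decides, a2 <= 1e-4 cannot be reported
  expect_true(is.null(components(f, "anisotropic")) ||
                components(f, "anisotropic")@amplitude > 1e-4)
})

test_that("the isotropic width series inverts to the generating D", {
  mt <- micsAcquisition()
  D <- 0.05
  mkFit <- function(lag) {
    s2px <- (4 * mt@pixelSize^2 + 2 * D * lag * mt@frameInterval) / mt@pixelSize^2
    iso <- new("GaussianComponent", amplitude = 0.01, center = c(0, 0),
               sigmaMajor = sqrt(s2px), sigmaMinor = sqrt(s2px), theta = 0,
               isIsotropic = TRUE)
    new("MixtureFit", components = list(iso), epsilon = 0, r2 = 0.95,
        lrtP = 0.5, classification = "isotropic", stderr = NA_real_,
        sse = 0, lagFrames = as.integer(lag),
        lagSeconds = lag * mt@frameInterval, converged = TRUE)
  }
  fits <- lapply(1:8, mkFit)
  est <- diffusionFromLagSeries(fits, mt)
  expect_equal(est$D, D, tolerance = 1e-10)
  expect_error(diffusionFromLagSeries(fits[1:3], mt), "at least 5")
})
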