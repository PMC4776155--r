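test_that("diffusive steps have the closed-form variance", {
  set.seed(50)
  mt <- micsAcquisition()
  cfg <- sceneConfig(nParticles = 10, brightness = 1, width = 256, height = 32,
                     nFrames = 1000, meta = mt, poissonNoise = FALSE)
  tr <- simulateTrajectories(diffusionModel(1), cfg, "frame")
  dx <- diff(tr@positions[, , 1])
  # wrap jumps are rare on this field; exclude them
  dx <- dx[abs(dx) < 5]
  expect_lt(abs(var(dx) / (2 * 1 * mt@frameInterval) - 1), 0.05)
  # D = 0 particles never move
  tr0 <- simulateTrajectories(diffusionModel(0), cfg, "frame")
  expect_equal(max(abs(diff(tr0@positions[, , 1]))), 0)
})

test_that("directed motion drifts at the configured velocity", {
  set.seed(51)
  mt <- micsAcquisition()
  cfg <- sceneConfig(nParticles = 400, brightness = 1, width = 256, height = 32,
                     nFrames = 22, meta = mt, poissonNoise = FALSE)
  tr <- simulateTrajectories(directedModel(c(1, 0), D = 0.01), cfg, "frame")
  t1 <- max(which(tr@times <= 1))
  disp <- tr@positions[t1, , ] - tr@positions[1, , ]
  disp <- disp[abs(disp[, 1]) < 5, ]     # drop wrap re-entries
  expect_equal(mean(disp[, 1]), 1 * tr@times[t1], tolerance = 0.05)
  expect_lt(abs(mean(disp[, 2])), 3 * sd(disp[, 2]) / sqrt(nrow(disp)) + 0.01)
})

test_that("bound sites switch with the configured residence and duty cycle", {
  set.seed(52)
  mt <- micsAcquisition()
  cfg <- sceneConfig(nParticles = 300, brightness = 1, width = 256, height = 32,
                     nFrames = 1000, meta = mt, poissonNoise = FALSE)
  tr <- simulateTrajectories(boundModel(residenceTime = 5), cfg, "frame")
  occ <- is.finite(tr@positions[, , 1])
  # equal on/off times: stationary occupancy ~ 50%
  expect_gt(mean(occ), 0.42); expect_lt(mean(occ), 0.58)
  # one on->off->on cycle per (5 + 5) s: ~10 switches over 49.6 s
  switches <- colSums(occ[-1, ] != occ[-nrow(occ), ])
  expect_gt(mean(switches), 6); expect_lt(mean(switches), 14)
  # a site never moves while occupied
  for (i in 1:10) {
    x <- tr@positions[occ[, i], i, 1]
    expect_equal(max(abs(diff(x))), 0)
  }
  # infinite residence = strictly static, always on
  trInf <- simulateTrajectories(boundModel(Inf), cfg, "frame")
  expect_true(all(is.finite(trInf@positions)))
  expect_equal(max(abs(diff(trInf@positions[, , 1]))), 0)
})

test_that("oscillating filament translates perpendicular to its axis", {
  mt <- micsAcquisition()
  cfg <- sceneConfig(nParticles = 11, brightness = 1, width = 256, height = 32,
                     nFrames = 100, meta = mt, poissonNoise = FALSE, seed = 53L)
  th <- 30 * pi / 180
  tr <- simulateTrajectories(filamentOscillatingModel(th, 2, 0.3, 1), cfg, "frame")
  p0 <- tr@positions[1, , ]
  # emitters are collinear along theta
  dirs <- atan2(p0[11, 2] - p0[1, 2], p0[11, 1] - p0[1, 1])
  expect_lt(angularErrDeg(dirs, th), 1e-6)
  # displacement over time is along theta + pi/2 with the configured amplitude
  d <- tr@positions[, 1, ] - matrix(p0[1, ], 100, 2, byrow = TRUE)
  along <- d[, 1] * cos(th) + d[, 2] * sin(th)
  perp <- -d[, 1] * sin(th) + d[, 2] * cos(th)
  expect_lt(max(abs(along)), 1e-12)
  expect_equal(max(abs(perp)), 0.3, tolerance = 0.01)
})

test_that("confined particles stay inside the oscillating box", {
  mt <- micsAcquisition()
  cfg <- sceneConfig(nParticles = 20, brightness = 1, width = 256, height = 32,
                     nFrames = 300, meta = mt, poissonNoise = FALSE, seed = 54L)
  model <- confinedOscillatingModel(D = 0.5, halfWidth = 0.4,
                                    amplitude = 0.2, period = 2)
  tr <- simulateTrajectories(model, cfg, "frame")
  for (i in 1:20) {
    dev <- tr@positions[, i, 1] - tr@positions[1, i, 1]
    expect_gte(min(dev), -0.4 - 1e-9)
    expect_lte(max(dev), 0.4 + 0.2 + 1e-9)
    devy <- tr@positions[, i, 2] - tr@positions[1, i, 2]
    expect_lte(max(abs(devy)), 0.4 + 1e-9)
  }
})

test_that("rendering reproduces the PSF for a static emitter, exactly twice", {
  mt <- micsAcquisition(width = 64, height = 32)
  cfg <- sceneConfig(nParticles = 1, brightness = 10, width = 64, height = 32,
                     nFrames = 3, meta = mt, poissonNoise = FALSE)
  # particle pinned at the centre of pixel (row 16, col 30)
  pos <- array(0, c(3, 1, 2))
  pos[, 1, 1] <- 29 * mt@pixelSize
  pos[, 1, 2] <- 15 * mt@pixelSize
  tr <- new("Trajectories", times = (0:2) * mt@frameInterval, positions = pos,
            sampling = "frame", model = diffusionModel(0))
  st <- renderFrames(tr, cfg)
  f <- frames(st)[1, , ]
  expect_equal(f[16, 30], 10, tolerance = 1e-12)        # peak = brightness
  expect_equal(f[16, 31], 10 * exp(-2 * 0.1^2 / 0.25^2), tolerance = 1e-12)
  expect_equal(f[16, 28], f[16, 32], tolerance = 1e-12) # symmetric
  # static scene: snapshot and raster renderers agree exactly
  posL <- array(0, c(3 * 32, 1, 2))
  posL[, 1, 1] <- 29 * mt@pixelSize; posL[, 1, 2] <- 15 * mt@pixelSize
  trL <- new("Trajectories", times = micsr:::lineTimes(cfg), positions = posL,
             sampling = "line", model = diffusionModel(0))
  expect_equal(frames(renderRaster(trL, cfg)), frames(st), tolerance = 1e-9)
})

test_that("identical scene configurations render bit-identical stacks", {
  mt <- micsAcquisition(width = 64, height = 32)
  cfg <- sceneConfig(nParticles = 50, brightness = 2, width = 64, height = 32,
                     nFrames = 10, meta = mt, poissonNoise = TRUE, seed = 55L)
  s1 <- simulateStack(diffusionModel(0.5), cfg, "line")
  s2 <- simulateStack(diffusionModel(0.5), cfg, "line")
  expect_identical(frames(s1), frames(s2))
})

test_that("photon count is conserved for interior emitters without noise", {
  mt <- micsAcquisition(width = 64, height = 64)
  cfg <- sceneConfig(nParticles = 5, brightness = 10, width = 64, height = 64,
                     nFrames = 4, meta = mt, poissonNoise = FALSE)
  set.seed(56)
  pos <- array(0, c(4, 5, 2))
  # emitters at least 3 w0 from every frame edge, static
  pos[, , 1] <- matrix(runif(5, 1, 5.3), 4, 5, byrow = TRUE)
  pos[, , 2] <- matrix(runif(5, 1, 5.3), 4, 5, byrow = TRUE)
  tr <- new("Trajectories", times = (0:3) * mt@frameInterval, positions = pos,
            sampling = "frame", model = boundModel(Inf))
  tot <- apply(frames(renderFrames(tr, cfg)), 1, sum)
  expect_lt(diff(range(tot)) / mean(tot), 0.01)
})
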