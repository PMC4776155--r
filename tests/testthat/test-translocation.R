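test_that("stand-still particles never move and a sealed envelope never absorbs", {
  cfg <- translocationConfig(modeProbs = c(0, 1, 0), tMax = 200, seed = 60L)
  res <- runTranslocation(cfg)
  expect_equal(max(abs(sweep(res@positions, 2, res@positions[1, ]))), 0)
  expect_equal(tail(res@nuclearCount, 1), 0L)
  sealed <- translocationConfig(modeProbs = c(1, 0, 0), permeability = 0,
                                tMax = 600, seed = 61L)
  expect_equal(max(runTranslocation(sealed)@nuclearCount), 0L)
})

test_that("diffusive steps match the configured variance", {
  cfg <- translocationConfig(modeProbs = c(1, 0, 0), D = 9.2, permeability = 0,
                             length = 1e6, nParticles = 400L, tMax = 300,
                             seed = 62L)
  res <- runTranslocation(cfg)
  steps <- diff(res@positions)
  expect_lt(abs(var(as.vector(steps)) / (2 * 9.2 * 1) - 1), 0.03)
  expect_lt(abs(mean(steps)), 0.05)
})

test_that("mass is conserved and uptake is monotone in permeability", {
  for (p0 in c(0.02, 0.1)) {
    cfg <- translocationConfig(permeability = p0, tMax = 400, seed = 63L)
    res <- runTranslocation(cfg)
    alive <- rowSums(!is.na(res@positions))
    expect_true(all(alive + res@nuclearCount == 500L))
    expect_true(all(diff(res@nuclearCount) >= 0L))
  }
  # common random numbers couple the runs: higher p0 never lags behind
  n1 <- runTranslocation(translocationConfig(permeability = 0.02, tMax = 400,
                                             seed = 63L))@nuclearCount
  n2 <- runTranslocation(translocationConfig(permeability = 0.1, tMax = 400,
                                             seed = 63L))@nuclearCount
  expect_true(all(n2 >= n1))
})

test_that("pure transport with an open envelope absorbs in ~L/(2v)", {
  cfg <- translocationConfig(modeProbs = c(0, 0, 1), permeability = 1,
                             dyneinVelocity = 1, tMax = 120, seed = 64L)
  res <- runTranslocation(cfg)
  absT <- apply(res@positions, 2, function(p) which(is.na(p))[1] - 1)
  expect_true(all(is.finite(absT)))                 # all 500 absorbed quickly
  expect_lt(abs(mean(absT) / 25 - 1), 0.1)          # uniform start: 50/(2*1) s
})

test_that("either diffusion or transport alone translocates most particles", {
  d <- runTranslocation(translocationConfig(modeProbs = c(1, 0, 0),
                                            permeability = 0.1, seed = 65L))
  t <- runTranslocation(translocationConfig(modeProbs = c(0, 0, 1),
                                            permeability = 0.1, seed = 66L))
  expect_gt(tail(d@nuclearCount, 1) / 500, 0.5)
  expect_gt(tail(t@nuclearCount, 1) / 500, 0.5)
})

test_that("runs are deterministic under a fixed seed", {
  cfg <- translocationConfig(tMax = 200, seed = 67L)
  r1 <- runTranslocation(cfg); r2 <- runTranslocation(cfg)
  expect_identical(r1@positions, r2@positions)
  expect_identical(r1@nuclearCount, r2@nuclearCount)
  expect_identical(translocationKymograph(r1), translocationKymograph(r2))
})

test_that("concavity metric separates convex from delayed decays", {
  tt <- 0:100
  expect_gt(concavityMetric(exp(-tt / 30), tt), 1)
  expect_lt(concavityMetric(1 / (1 + exp((tt - 50) / 10)), tt), 1)
  expect_error(concavityMetric(1 - 0.001 * tt, tt), "insufficient depletion")
  expect_error(concavityMetric(exp(-(0:5))), "too short")
})
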