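test_that("bleach correction restores every frame mean to f(0)", {
  set.seed(2)
  mt <- testMeta(8, 8)
  base <- matrix(runif(64, 10, 30), 8, 8)
  arr <- array(0, c(60, 8, 8))
  for (t in 1:60) arr[t, , ] <- base * exp(-0.008 * (t - 1))
  out <- bleachCorrect(imageStack(arr, mt))
  means <- apply(frames(out), 1, mean)
  expect_lt(max(abs(means / mean(base) - 1)), 1e-6)
  # constant stacks are returned unchanged; the correction is idempotent
  flat <- imageStack(array(7, c(5, 8, 8)), mt)
  expect_equal(frames(bleachCorrect(flat)), frames(flat))
  expect_equal(frames(bleachCorrect(out)), frames(out), tolerance = 1e-12)
})

test_that("bleach correction stabilizes mean and variance of a Poisson stack", {
  set.seed(3)
  mt <- testMeta(32, 32)
  T <- 300
  arr <- array(0, c(T, 32, 32))
  lam0 <- 80
  decay <- exp(log(0.7) * (seq_len(T) - 1) / (T - 1))   # 30% bleach
  for (t in seq_len(T)) arr[t, , ] <- rpois(1024, lam0 * decay[t])
  out <- bleachCorrect(imageStack(arr, mt))
  tt <- seq_len(T)
  frameVar <- function(a) apply(a, 1, function(m) var(as.vector(m)))
  fitM <- lm(apply(frames(out), 1, mean) ~ tt)
  fitV <- lm(frameVar(frames(out)) ~ tt)
  # slope of corrected mean and variance indistinguishable from zero
  expect_lt(abs(summary(fitM)$coefficients["tt", "t value"]), 3)
  expect_lt(abs(summary(fitV)$coefficients["tt", "t value"]), 3)
  # uncorrected stack, for contrast, has a strongly negative mean slope
  fit0 <- lm(apply(arr, 1, mean) ~ tt)
  expect_lt(summary(fit0)$coefficients["tt", "t value"], -10)
})

test_that("time-average removal leaves zero-mean fluctuations", {
  set.seed(4)
  mt <- testMeta(6, 6)
  img <- matrix(runif(36, 5, 9), 6, 6)
  static <- imageStack(array(rep(img, each = 8), c(8, 6, 6)), mt)
  fl <- removeTimeAverage(static)
  expect_equal(max(abs(fl@deltas)), 0)
  # one pixel alternating m +/- a
  arr <- array(rep(img, each = 8), c(8, 6, 6))
  arr[, 3, 4] <- 7 + c(-1, 1)
  fl2 <- removeTimeAverage(imageStack(arr, mt))
  expect_equal(fl2@deltas[, 3, 4], rep(c(-1, 1), 4))
  expect_equal(max(abs(fl2@deltas[, -3, ])), 0)
  # defining property + idempotence on any stack
  arr3 <- array(runif(8 * 36, 1, 4), c(8, 6, 6))
  fl3 <- removeTimeAverage(imageStack(arr3, mt))
  expect_lt(max(abs(apply(fl3@deltas, c(2, 3), mean))), 1e-9 * max(arr3))
  fl4 <- removeTimeAverage(imageStack(fl3@deltas - min(fl3@deltas) + 1, mt))
  expect_equal(fl4@deltas, fl3@deltas, tolerance = 1e-12)
})

test_that("moving-average high-pass removes slow trends", {
  mt <- testMeta(4, 4)
  flat <- imageStack(array(3, c(30, 4, 4)), mt)
  expect_equal(max(abs(movingAverageHighpass(flat, 10)@deltas)), 0)
  # a linear ramp is captured by the centred local mean at interior frames
  arr <- array(1, c(30, 4, 4))
  arr[, 2, 2] <- seq(1, 30)
  fl <- movingAverageHighpass(imageStack(arr, mt), 10)
  expect_lt(max(abs(fl@deltas[10:21, 2, 2])), 0.2)
  expect_error(movingAverageHighpass(imageStack(array(1, c(5, 4, 4)), mt), 10),
               "shorter")
  # sinusoid attenuation matches a brute-force centred moving average
  T <- 40
  x <- 5 + sin(2 * pi * seq_len(T) / 4)
  arr2 <- array(rep(x, 16), c(T, 4, 4))
  fl2 <- movingAverageHighpass(imageStack(arr2, mt), 10)
  half <- 5L
  bf <- vapply(seq_len(T), function(t) {
    k <- min(t - max(t - half, 1), min(t + half, T) - t)
    x[t] - mean(x[(t - k):(t + k)])
  }, 1)
  bf <- bf - mean(bf)
  expect_equal(fl2@deltas[, 1, 1], bf, tolerance = 1e-12)
})

test_that("immobile emitters with photon noise leave no lagged correlation", {
  set.seed(5)
  mt <- testMeta(16, 16)
  img <- matrix(rexp(256, 1 / 50), 16, 16)
  arr <- array(rpois(200 * 256, rep(img, each = 200)), c(200, 16, 16))
  fl <- removeTimeAverage(imageStack(arr, mt))
  cm <- sticsCorrelate(fl, lags = 1L, maxShift = 4L)
  # null scale from temporally shuffled frames (breaks any real lag structure)
  perm <- sample(200)
  flp <- fl
  flp@deltas <- fl@deltas[perm, , ]
  null <- sticsCorrelate(flp, lags = 1L, maxShift = 4L)
  expect_lt(abs(surface(cm)["0", "0"]), 3 * sd(surface(null)) + 1e-12)
})
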