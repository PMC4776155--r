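# Brute-force oracles and small scene builders shared across tests.

# direct double-loop normalized spatial autocorrelation (non-periodic)
autocorrOracle <- function(f, maxRow, maxCol) {
  h <- nrow(f); w <- ncol(f); m <- mean(f)
  out <- matrix(0, 2 * maxRow + 1, 2 * maxCol + 1)
  for (dr in -maxRow:maxRow) for (dc in -maxCol:maxCol) {
    s <- 0; n <- 0
    for (r in 1:h) for (c in 1:w) {
      r2 <- r + dr; c2 <- c + dc
      if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w) {
        s <- s + f[r, c] * f[r2, c2]; n <- n + 1
      }
    }
    out[dr + maxRow + 1, dc + maxCol + 1] <- s / n / m^2 - 1
  }
  dimnames(out) <- list(psi = as.character(-maxRow:maxRow),
                        xi = as.character(-maxCol:maxCol))
  out
}

# direct quadruple-loop STICS oracle on a FluctuationStack
sticsOracle <- function(fluct, lag, maxShift) {
  d <- fluct@deltas
  m <- apply(d, 1, mean) + mean(fluct@meanImage)
  T <- dim(d)[1]; h <- dim(d)[2]; w <- dim(d)[3]
  out <- matrix(0, 2 * maxShift + 1, 2 * maxShift + 1)
  for (dr in -maxShift:maxShift) for (dc in -maxShift:maxShift) {
    tot <- 0
    for (t in 1:(T - lag)) {
      s <- 0; n <- 0
      for (r in 1:h) for (c in 1:w) {
        r2 <- r + dr; c2 <- c + dc
        if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w) {
          s <- s + d[t, r, c] * d[t + lag, r2, c2]; n <- n + 1
        }
      }
      tot <- tot + s / n / (m[t] * m[t + lag])
    }
    out[dr + maxShift + 1, dc + maxShift + 1] <- tot / (T - lag)
  }
  dimnames(out) <- list(psi = as.character(-maxShift:maxShift),
                        xi = as.character(-maxShift:maxShift))
  out
}

# analytic two-component mixture surface on a (2m+1)^2 grid
mixtureSurface <- function(a1, s1, eps, a2 = 0, mux = 0, muy = 0,
                           sM = 1, sm = 1, th = 0, m = 8,
                           noiseSD = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  xi <- -m:m
  XI <- matrix(xi, 2 * m + 1, 2 * m + 1, byrow = TRUE)
  PSI <- matrix(xi, 2 * m + 1, 2 * m + 1)
  v <- a1 * exp(-(XI^2 + PSI^2) / (2 * s1^2)) + eps
  if (a2 != 0) {
    u <- cos(th) * (XI - mux) + sin(th) * (PSI - muy)
    q <- -sin(th) * (XI - mux) + cos(th) * (PSI - muy)
    v <- v + a2 * exp(-0.5 * (u^2 / sM^2 + q^2 / sm^2))
  }
  if (noiseSD > 0) v <- v + stats::rnorm(length(v), 0, noiseSD)
  dimnames(v) <- list(psi = as.character(xi), xi = as.character(xi))
  v
}

# small generic acquisition metadata for unit tests
testMeta <- function(width = 8, height = 8) {
  acquisitionMeta(pixelSize = 0.1, pixelDwell = 1e-6,
                  lineTime = width * 1e-6 + 1e-5,
                  frameInterval = height * (width * 1e-6 + 1e-5) + 1e-3)
}

angularErrDeg <- function(a, b) {
  d <- abs((a - b) %% pi)
  min(d, pi - d) * 180 / pi
}
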