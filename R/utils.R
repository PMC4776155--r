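# Internal numerics shared by the correlation modules.

# Next power of two >= n (FFT-friendly padding).
nextPow2 <- function(n) 2L^as.integer(ceiling(log2(n)))

# Non-periodic cross-correlation numerator via zero-padded FFT:
#   num[dr, dc] = sum_{r,c} A[r, c] * B[r + dr, c + dc]
# for dr in -maxRow..maxRow, dc in -maxCol..maxCol. Returns the
# (2*maxRow+1) x (2*maxCol+1) matrix with dimnames giving the shifts.
xcorrNumerator <- function(A, B, maxRow, maxCol) {
  stopifnot(identical(dim(A), dim(B)))
  h <- nrow(A); w <- ncol(A)
  stopifnot(maxRow < h, maxCol < w)
  ph <- nextPow2(h + maxRow)
  pw <- nextPow2(w + maxCol)
  Ap <- matrix(0, ph, pw); Ap[1:h, 1:w] <- A
  Bp <- matrix(0, ph, pw); Bp[1:h, 1:w] <- B
  cc <- Re(stats::fft(Conj(stats::fft(Ap)) * stats::fft(Bp), inverse = TRUE)) /
    (ph * pw)
  wrapIndex(cc, maxRow, maxCol)
}

# Extract the centred shift block from a wrapped (FFT-order) correlation.
wrapIndex <- function(cc, maxRow, maxCol) {
  ph <- nrow(cc); pw <- ncol(cc)
  ri <- c((ph - maxRow + 1L):ph, 1L:(maxRow + 1L))
  ci <- c((pw - maxCol + 1L):pw, 1L:(maxCol + 1L))
  out <- cc[ri, ci, drop = FALSE]
  dimnames(out) <- list(psi = as.character(-maxRow:maxRow),
                        xi  = as.character(-maxCol:maxCol))
  out
}

# Number of in-bounds pixel pairs per shift for an h x w frame
# (non-periodic averaging): (h - |dr|) * (w - |dc|).
pairCounts <- function(h, w, maxRow, maxCol) {
  outer(h - abs(-maxRow:maxRow), w - abs(-maxCol:maxCol))
}

# Shift axes of a centred surface.
shiftAxes <- function(S) {
  list(psi = as.integer(rownames(S)), xi = as.integer(colnames(S)))
}

# Angular distance on the half-circle (orientations are mod pi).
angularDistance <- function(a, b) {
  d <- abs((a - b) %% pi)
  pmin(d, pi - d)
}

# Central-difference Jacobian of fn (vector-valued) at par.
numericJacobian <- function(fn, par, eps = 1e-6) {
  f0 <- fn(par)
  J <- matrix(0, length(f0), length(par))
  for (j in seq_along(par)) {
    h <- eps * max(1, abs(par[j]))
    up <- par; up[j] <- par[j] + h
    dn <- par; dn[j] <- par[j] - h
    J[, j] <- (fn(up) - fn(dn)) / (2 * h)
  }
  J
}

# Parameter standard errors from the Gauss-Newton Hessian of an SSE
# objective: cov = (sse / (n - p)) * (J'J)^{-1}. Returns NAs when singular.
sseStdErr <- function(residFn, par, sse) {
  n <- length(residFn(par)); p <- length(par)
  se <- rep(NA_real_, p)
  if (n <= p) return(se)
  J <- numericJacobian(residFn, par)
  JtJ <- crossprod(J)
  cv <- tryCatch(solve(JtJ) * sse / (n - p), error = function(e) NULL)
  if (!is.null(cv)) {
    d <- diag(cv)
    se[d >= 0] <- sqrt(d[d >= 0])
  }
  se
}

# R^2 of a fit against the surface values.
rSquared <- function(obs, fitted) {
  sst <- sum((obs - mean(obs))^2)
  if (sst <= 0) return(NA_real_)
  1 - sum((obs - fitted)^2) / sst
}
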