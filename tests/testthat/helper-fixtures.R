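# Shared fixtures: small grids, noise-free configs, tiny datasets.

tiny_grid <- function(start = 4000, end = 4400, step = 8)
  wavenumberGrid(start, end, step)

# a noise specification with every stochastic term switched off
zero_noise <- function() {
  ns <- defaultNoise()
  ns$additive_sd <- 0
  ns$scatter_gain_sd <- 0
  ns$baseline_offset_sd <- 0
  ns$baseline_slope_sd <- 0
  ns$reference_rsd[] <- 0
  ns$moisture_ref_sd <- 0
  ns
}

noise_free_config <- function(nBatches = 4L, duration = 300, seed = 99L)
  syntheticConfig(noise = zero_noise(), nBatches = nBatches,
                  duration = duration, seed = seed)

# small random SpectraSet on a short grid
random_spectra <- function(n = 6, grid = tiny_grid(), seed = 1) {
  set.seed(seed)
  nu <- gridSeq(grid)
  SpectraSet(matrix(rnorm(n * length(nu)), n), nu,
             sampleId = sprintf("s%02d", seq_len(n)),
             batchId = rep("b1", n), steamTime = 30 * seq_len(n))
}

# independent OLS oracle via the normal equations (with intercept)
ols_predict <- function(X, y, Xnew = X) {
  Xc <- cbind(1, X)
  beta <- solve(crossprod(Xc), crossprod(Xc, y))
  as.numeric(cbind(1, Xnew) %*% beta)
}

# naive Savitzky-Golay oracle: explicit polynomial least squares around every
# point (truncated window near edges, reduced order when underdetermined)
savgol_oracle <- function(m, window, polyorder, deriv, step = 1) {
  h <- (window - 1) %/% 2
  n <- ncol(m)
  out <- matrix(0, nrow(m), n)
  for (i in seq_len(n)) {
    idx <- max(1, i - h):min(n, i + h)
    q <- min(polyorder, length(idx) - 1)
    u <- idx - i
    for (r in seq_len(nrow(m))) {
      fit <- stats::lm.fit(outer(u, 0:q, `^`), m[r, idx])
      out[r, i] <- fit$coefficients[deriv + 1] * factorial(deriv)
    }
  }
  out / step^deriv
}

# naive Kennard-Stone oracle with explicit loops
ks_oracle <- function(m, ncal) {
  n <- nrow(m)
  D <- as.matrix(dist(m))
  best <- c(NA, NA); bd <- -Inf
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (D[i, j] > bd) { bd <- D[i, j]; best <- c(i, j) }
  sel <- best
  while (length(sel) < ncal) {
    cand <- setdiff(seq_len(n), sel)
    md <- sapply(cand, function(c) min(D[c, sel]))
    sel <- c(sel, cand[which.max(md)])
  }
  sel
}

# plain-R PLS1 (textbook NIPALS), independent of the package's compiled path;
# returns the coefficient vector and centring constants for exactly k LVs
r_pls1 <- function(X, y, k) {
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm); yc <- y - ym
  p <- ncol(X)
  W <- P <- matrix(0, p, k); q <- numeric(k)
  for (a in seq_len(k)) {
    w <- crossprod(Xc, yc)
    w <- w / sqrt(sum(w^2))
    t <- Xc %*% w
    tt <- sum(t^2)
    pl <- crossprod(Xc, t) / tt
    qa <- sum(yc * t) / tt
    Xc <- Xc - t %*% t(pl)
    yc <- yc - qa * t
    W[, a] <- w; P[, a] <- pl; q[a] <- qa
  }
  b <- W %*% solve(crossprod(P, W), q)
  list(coef = as.numeric(b), x_mean = xm, y_mean = ym)
}

# naive double-loop LOO RMSECV oracle built on the plain-R PLS
loocv_oracle_pls <- function(X, y, maxk) {
  n <- nrow(X)
  errs <- matrix(0, n, maxk)
  for (i in seq_len(n)) for (k in seq_len(maxk)) {
    fit <- r_pls1(X[-i, , drop = FALSE], y[-i], k)
    errs[i, k] <- fit$y_mean +
      sum((X[i, ] - fit$x_mean) * fit$coef) - y[i]
  }
  sqrt(colMeans(errs^2))
}
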