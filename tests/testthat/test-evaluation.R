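test_that("rmse: closed form, conservation, permutation invariance", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(25 / 2))
  set.seed(60)
  y <- rnorm(15); yh <- rnorm(15)
  expect_equal(rmse(y, yh)^2 * 15, sum((y - yh)^2), tolerance = 1e-10)
  p <- sample(15)
  expect_equal(rmse(y[p], yh[p]), rmse(y, yh))
  expect_error(rmse(1:3, 1:4), "length mismatch")
})

test_that("the two R2 variants separate under affine miscalibration", {
  set.seed(61)
  y <- rnorm(20)
  expect_equal(rSquared(y, y), 1.0)
  yh <- 2 * y + 3
  expect_equal(rSquared(y, yh), 1.0, tolerance = 1e-12)
  expect_lt(rSquared(y, yh, method = "ss"), 1)
  # orthogonal prediction has zero Pearson R2
  z <- rnorm(20)
  z <- z - mean(z)
  yc <- y - mean(y)
  z <- z - yc * sum(z * yc) / sum(yc^2)
  expect_equal(rSquared(y, z + mean(y)), 0, tolerance = 1e-12)
  expect_error(rSquared(rep(1, 5), rnorm(5)), "zero variance")
  # regression case: both variants agree for the least-squares fit
  X <- matrix(rnorm(20 * 3), 20)
  fit <- lm(y ~ X)
  expect_equal(rSquared(y, fitted(fit)),
               rSquared(y, fitted(fit), method = "ss"), tolerance = 1e-12)
})

test_that("rpd is the sd-to-error ratio with guarded degeneracy", {
  expect_equal(rpd(2.0, 0.5), 4.0)
  expect_equal(rpd(0.7, 0.7), 1.0)
  expect_equal(rpd(2 * 1.3, 0.5), 2 * rpd(1.3, 0.5))
  expect_error(rpd(1, 0), "rmsep")
})

test_that("rsep is the root relative squared error in percent", {
  expect_equal(rsep(c(1, 2), c(1, 2)), 0)
  expect_equal(rsep(1, 1.1), 10, tolerance = 1e-10)
  set.seed(62)
  y <- runif(10, 1, 2); yh <- y + rnorm(10, 0, 0.1)
  expect_equal(rsep(3 * y, 3 * yh), rsep(y, yh), tolerance = 1e-12)
  expect_error(rsep(c(0, 0), c(1, 1)), "all-zero")
})

test_that("paired t-test matches the closed form and its CDF oracle", {
  set.seed(63)
  a <- rnorm(10); b <- rnorm(10)
  got <- pairedTTest(a, b)
  d <- a - b
  tstat <- mean(d) / (sd(d) / sqrt(10))
  p <- 2 * pt(abs(tstat), df = 9, lower.tail = FALSE)
  expect_equal(got$statistic, tstat, tolerance = 1e-10)
  expect_lt(abs(got$p_value - p), 1e-6)
  same <- pairedTTest(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(pairedTTest(a, a - 1), "zero variance")
  expect_error(pairedTTest(1:3, 1:4), "equal length")
})

test_that("variance F-test is symmetric and matches the F CDF oracle", {
  set.seed(64)
  a <- rnorm(12, sd = 2); b <- rnorm(9)
  got <- varianceFTest(a, b)
  f <- max(var(a), var(b)) / min(var(a), var(b))
  df <- if (var(a) >= var(b)) c(11, 8) else c(8, 11)
  p <- min(1, 2 * pf(f, df[1], df[2], lower.tail = FALSE))
  expect_equal(got$statistic, f, tolerance = 1e-12)
  expect_lt(abs(got$p_value - p), 1e-6)
  swapped <- varianceFTest(b, a)
  expect_equal(swapped$statistic, got$statistic)
  expect_equal(swapped$p_value, got$p_value)
  # var.test cross-check (two-sided p invariant to orientation)
  expect_equal(got$p_value, var.test(a, b)$p.value, tolerance = 1e-10)
  same <- varianceFTest(a, a)
  expect_equal(same$statistic, 1)
  expect_equal(same$p_value, 1)
  expect_error(varianceFTest(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("model reports are internally consistent and guard leakage", {
  d <- generateDataset(noise_free_config(nBatches = 4, duration = 300))
  sp <- kennardStone(absorbance(d$spectra), 32)   # 44 samples: 32/12
  cal <- d$spectra[, sp@calibration]
  val <- d$spectra[, sp@validation]
  y <- d$reference$gastrodin
  yc <- y[sp@calibration]; yv <- y[sp@validation]
  m <- fitPLS(absorbance(cal), yc, length(defaultComponents()),
              property = "gastrodin", wavenumbers = wavenumbers(d$spectra))
  rep <- modelReport(m, cal, yc, val, yv)
  # perfect-fit limit on noise-free data
  expect_gt(rep@rc2, 1 - 1e-9)
  expect_gt(rep@rp2, 1 - 1e-9)
  expect_lt(rep@rmsec, 1e-7)
  expect_lt(rep@rmsep, 1e-7)
  expect_equal(rep@rpd, sd(yv) / rep@rmsep, tolerance = 1e-12)
  df <- as.data.frame(rep)
  expect_named(df, c("property", "method", "Rc2", "RMSEC", "RMSECV", "Rp2",
                     "RMSEP", "RPD", "RSEP", "LVs"))
  expect_error(modelReport(m, cal, yc, cal, yc), "leakage")
})
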