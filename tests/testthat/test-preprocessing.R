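test_that("MSC fit stores the calibration mean and is order-invariant", {
  s <- random_spectra(n = 6, seed = 11)
  st <- mscFit(s)
  expect_equal(st@reference, unname(colMeans(absorbance(s))),
               ignore_attr = TRUE)
  perm <- sample(6)
  expect_equal(mscFit(absorbance(s)[perm, ])@reference, st@reference)
  expect_error(mscFit(absorbance(s)[1, , drop = FALSE]), "at least two")
  two <- rbind(absorbance(s)[1, ], absorbance(s)[1, ])
  expect_equal(mscFit(two)@reference, unname(absorbance(s)[1, ]),
               ignore_attr = TRUE)
})

test_that("MSC inverts per-spectrum affine distortions exactly", {
  s <- random_spectra(n = 5, seed = 12)
  st <- mscFit(s)
  m <- st@reference
  # x = m maps to m; x = 2m + 1 maps to m
  expect_equal(as.numeric(mscApply(st, rbind(m))), m)
  expect_equal(as.numeric(mscApply(st, rbind(2 * m + 1))), m)
  # x = 3m - 0.5 + r with r orthogonal to [1, m]: output is m + r/3
  set.seed(13)
  r <- rnorm(length(m))
  Q <- qr.Q(qr(cbind(1, m)))
  r <- r - Q %*% crossprod(Q, r)          # project out intercept and m
  x <- 3 * m - 0.5 + as.numeric(r)
  got <- as.numeric(mscApply(st, rbind(x)))
  # independent oracle: generic linear regression of x on m
  fit <- lm(x ~ m)
  expect_equal(unname(coef(fit)), c(-0.5, 3), tolerance = 1e-10)
  expect_equal(got, m + as.numeric(r) / 3, tolerance = 1e-10)
})

test_that("MSC and SNV cancel any affine distortion a + b*x", {
  s <- random_spectra(n = 8, seed = 14)
  X <- absorbance(s)
  a <- rnorm(8)
  b <- runif(8, 0.5, 2)
  Xd <- X * b + a
  st <- mscFit(X)
  expect_equal(mscApply(st, Xd), mscApply(st, X), tolerance = 1e-10)
  expect_equal(snv(Xd), snv(X), tolerance = 1e-10)
})

test_that("SNV standardizes rows and is idempotent", {
  expect_equal(as.numeric(snv(rbind(c(1, 2, 3)))), c(-1, 0, 1))
  X <- absorbance(random_spectra(n = 7, seed = 15))
  Z <- snv(X)
  expect_lt(max(abs(rowMeans(Z))), 1e-12)
  expect_lt(max(abs(apply(Z, 1, sd) - 1)), 1e-12)
  expect_equal(snv(Z), Z, tolerance = 1e-12)
  Xz <- X
  Xz[3, ] <- 2.5
  expect_error(snv(Xz), "zero variance")
})

test_that("Savitzky-Golay reproduces polynomials and their derivatives", {
  g <- tiny_grid(4000, 4800, 8)
  nu <- gridSeq(g)
  u <- (nu - 4400) / 100                   # well-scaled polynomial argument
  X <- rbind(2 + 3 * u - 0.5 * u^2, 1 - u + 0.25 * u^2)
  s <- SpectraSet(X, nu)
  sm <- savgol(s, window = 9, polyorder = 2, deriv = 0)
  expect_equal(absorbance(sm), absorbance(s), tolerance = 1e-10)
  # derivative of a linear ramp x(nu) = nu is 1 everywhere (per cm-1 scaling)
  lin <- SpectraSet(rbind(nu, 2 * nu), nu)
  d1 <- savgol(lin, window = 7, polyorder = 2, deriv = 1)
  expect_equal(absorbance(d1), rbind(rep(1, length(nu)), rep(2, length(nu))),
               tolerance = 1e-9, ignore_attr = TRUE)
  # constant spectrum is preserved by deriv = 0
  cst <- matrix(3.2, 2, length(nu))
  expect_equal(savgol(cst, 5, 2, 0), cst, tolerance = 1e-12)
})

test_that("window-5 quadratic smoothing has the classic center weights", {
  n <- 31
  imp <- matrix(0, 1, n)
  imp[1, 16] <- 1
  sm <- savgol(imp, window = 5, polyorder = 2, deriv = 0)
  expect_equal(as.numeric(sm[1, 14:18]), c(-3, 12, 17, 12, -3) / 35,
               tolerance = 1e-12)
})

test_that("SG matches the per-window least-squares oracle incl. edges", {
  set.seed(16)
  m <- matrix(rnorm(3 * 25), 3, 25)
  for (window in c(5, 7, 9)) for (po in 2:3) for (dv in 0:2) {
    if (dv > po) next
    got <- savgol(m, window, po, dv, step = 8)
    want <- savgol_oracle(m, window, po, dv, step = 8)
    expect_lt(max(abs(got - want)), 1e-10)
  }
})

test_that("operators are row-wise independent (permutation equivariance)", {
  X <- absorbance(random_spectra(n = 6, seed = 17))
  perm <- c(4, 1, 6, 2, 5, 3)
  expect_equal(snv(X)[perm, ], snv(X[perm, ]))
  expect_equal(savgol(X, 7, 2, 1)[perm, ], savgol(X[perm, ], 7, 2, 1))
  st <- mscFit(X)
  expect_equal(mscApply(st, X)[perm, ], mscApply(st, X[perm, ]))
})

test_that("chains apply in order and never fit on target data", {
  s <- random_spectra(n = 5, seed = 18)
  # empty chain is the identity
  fa <- chainFitApply(preprocessChain(), s, s)
  expect_equal(absorbance(fa$target), absorbance(s))
  # MSC maps the calibration mean row to itself
  st <- fitChain(preprocessChain(mscStep()), s)
  mrow <- rbind(st@steps[[1]]@reference)
  expect_equal(as.numeric(applyChain(st, mrow)), as.numeric(mrow))
  # sentinel: validation rows must not influence the fitted MSC state
  cal <- random_spectra(n = 5, seed = 19)
  sentinel <- SpectraSet(absorbance(cal) * 1e6, wavenumbers(cal),
                         sampleId = sampleId(cal), batchId = batchId(cal),
                         steamTime = steamTime(cal))
  ch <- parseChain("MSC+SG9+FD")
  f1 <- fitChain(ch, cal)
  out1 <- applyChain(f1, sentinel)
  f2 <- chainFitApply(ch, cal, sentinel)
  expect_equal(f2$chain@steps[[1]]@reference, f1@steps[[1]]@reference)
  expect_equal(absorbance(f2$target), absorbance(out1))
})

test_that("chain labels parse to the expected steps", {
  ch <- parseChain("MSC+SG9+FD")
  expect_length(ch@steps, 2)
  expect_s4_class(ch@steps[[1]], "MSCStep")
  sg <- ch@steps[[2]]
  expect_identical(c(sg@window, sg@polyorder, sg@deriv), c(9L, 2L, 1L))
  sg2 <- parseChain("MSC+SG7+SD")@steps[[2]]
  expect_identical(c(sg2@window, sg2@deriv), c(7L, 2L))
  expect_error(parseChain("MSC+XYZ"), "unknown")
  expect_error(preprocessChain(sgStep(window = 4)), "odd")
  expect_error(preprocessChain(sgStep(window = 5, polyorder = 5)), "smaller")
})
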