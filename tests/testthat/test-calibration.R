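test_that("PLS on an exactly proportional single predictor is exact", {
  m <- fitPLS(matrix(c(1, 2, 3), ncol = 1), c(2, 4, 6), 1)
  expect_equal(m@coefficients, 2.0, tolerance = 1e-12)
  pred <- predict(m, matrix(c(1, 2, 3), ncol = 1), preprocessed = TRUE)
  expect_equal(pred, c(2, 4, 6), tolerance = 1e-12)
})

test_that("PLS and PCR reduce to OLS in the full-component limit", {
  set.seed(30)
  X <- matrix(rnorm(30 * 5), 30)
  y <- X %*% rnorm(5) + rnorm(30, 0, 0.3)
  want <- ols_predict(X, y)
  pls <- fitPLS(X, y, 5)
  expect_equal(predict(pls, X, preprocessed = TRUE), want, tolerance = 1e-8)
  pcr <- fitPCR(X, y, 5)
  expect_equal(predict(pcr, X, preprocessed = TRUE), want, tolerance = 1e-8)
})

test_that("NIPALS score vectors are mutually orthogonal", {
  set.seed(31)
  X <- matrix(rnorm(25 * 12), 25)
  y <- rnorm(25)
  fit <- nipalsPls(X, y, 6)
  G <- crossprod(fit$scores)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
})

test_that("the compiled NIPALS agrees with a plain-R NIPALS", {
  set.seed(32)
  X <- matrix(rnorm(18 * 9), 18)
  y <- rnorm(18)
  for (k in c(1, 3, 5)) {
    ours <- nipalsPls(X, y, k)
    ref <- r_pls1(X, y, k)
    expect_equal(ours$coefficients[, k], ref$coef, tolerance = 1e-9)
  }
})

test_that("PCR captures a dominant y-colinear direction with one component", {
  set.seed(33)
  t <- rnorm(40, sd = 5)
  d <- rnorm(6)
  d <- d / sqrt(sum(d^2))
  X <- outer(t, d)                        # rank-1, exactly along d
  y <- 3 * t
  m <- fitPCR(X, y, 1)
  expect_lt(rmse(y, predict(m, X, preprocessed = TRUE)), 1e-8)
  L <- attr(m, "loadings")
  expect_equal(sum(L[, 1]^2), 1.0, tolerance = 1e-10)
})

test_that("SMLR recovers a single informative wavelength exactly", {
  set.seed(34)
  X <- matrix(rnorm(60 * 10), 60)
  y <- 3 * X[, 5]
  m <- fitSMLR(X, y, maxTerms = 5)
  expect_identical(m@selectedVariables, 5L)
  expect_equal(m@coefficients, 3.0, tolerance = 1e-10)
  # exhaustive best single-variable subset agrees
  sse <- sapply(seq_len(10), function(j)
    sum(lm(y ~ X[, j])$residuals^2))
  expect_identical(which.min(sse), 5L)
  # an exact duplicate of the informative column is never co-selected
  Xd <- cbind(X, X[, 5])
  md <- fitSMLR(Xd, y, maxTerms = 5)
  expect_identical(md@selectedVariables, 5L)
  # no informative variable at all
  expect_error(fitSMLR(matrix(rnorm(40), 20), rnorm(20), fEnter = 1e6),
               "no informative variable")
  expect_error(fitSMLR(X, y, fEnter = 3, fRemove = 4), "fRemove")
})

test_that("LOO RMSECV finds the generative rank and matches the oracle", {
  set.seed(35)
  # noise-free rank-2 response
  T2 <- matrix(rnorm(24 * 2), 24)
  P2 <- matrix(rnorm(2 * 9), 2)
  X <- T2 %*% P2
  y <- T2 %*% c(1.5, -2)
  cv <- loocvRMSECV(X, y, 5)
  expect_identical(cv$chosen_k, 2L)
  expect_lt(cv$rmsecv_by_k[2], 1e-8)
  expect_lt(cv$rmsecv_by_k[5], 1e-8)
  # degenerate response guard
  expect_error(loocvRMSECV(X, rep(1, 24), 3), "no variance")
  # naive double-loop oracle, 12-sample instance
  set.seed(36)
  Xs <- matrix(rnorm(12 * 6), 12)
  ys <- rnorm(12)
  cv2 <- loocvRMSECV(Xs, ys, 4)
  expect_lt(max(abs(cv2$rmsecv_by_k - loocv_oracle_pls(Xs, ys, 4))), 1e-10)
})

test_that("PCR LOO-CV matches a naive prcomp-and-lm oracle", {
  set.seed(41)
  X <- matrix(rnorm(14 * 6), 14)
  y <- rnorm(14)
  cv <- loocvRMSECV(X, y, 4, method = "pcr")
  errs <- matrix(0, 14, 4)
  for (i in 1:14) {
    pc <- prcomp(X[-i, ], center = TRUE, scale. = FALSE)
    for (k in 1:4) {
      fit <- lm(y[-i] ~ pc$x[, 1:k, drop = FALSE])
      snew <- (X[i, ] - pc$center) %*% pc$rotation[, 1:k, drop = FALSE]
      errs[i, k] <- coef(fit)[1] + sum(coef(fit)[-1] * snew) - y[i]
    }
  }
  expect_lt(max(abs(cv$rmsecv_by_k - sqrt(colMeans(errs^2)))), 1e-10)
})

test_that("ties in the RMSECV argmin resolve to the smallest k", {
  cv <- list(rmsecv_by_k = c(0.5, 0.2, 0.2, 0.3))
  expect_identical(which.min(cv$rmsecv_by_k), 2L)  # contract used internally
  set.seed(37)
  T2 <- matrix(rnorm(20 * 2), 20)
  X <- T2 %*% matrix(rnorm(8 * 2), 2)
  y <- T2 %*% c(1, 1)
  cv2 <- loocvRMSECV(X, y, 6)
  expect_identical(cv2$chosen_k, 2L)   # all k >= 2 are ~0; parsimony wins
})

test_that("training RMSEC is non-increasing in PLS components", {
  set.seed(38)
  X <- matrix(rnorm(30 * 10), 30)
  y <- rnorm(30)
  errs <- sapply(1:8, function(k)
    rmse(y, predict(fitPLS(X, y, k), X, preprocessed = TRUE)))
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("fits are invariant to permutations of the training rows", {
  set.seed(39)
  X <- matrix(rnorm(25 * 7), 25)
  y <- rnorm(25)
  perm <- sample(25)
  m1 <- fitPLS(X, y, 3)
  m2 <- fitPLS(X[perm, ], y[perm], 3)
  expect_equal(m1@coefficients, m2@coefficients, tolerance = 1e-9)
  ys <- X[, 2] * 2 + rnorm(25, 0, 0.01)
  s1 <- fitSMLR(X, ys)
  s2 <- fitSMLR(X[perm, ], ys[perm])
  expect_identical(s1@selectedVariables, s2@selectedVariables)
  expect_equal(s1@coefficients, s2@coefficients, tolerance = 1e-10)
})

test_that("prediction contract: stored fields alone reproduce predictions", {
  set.seed(40)
  X <- matrix(rnorm(20 * 6), 20)
  y <- rnorm(20)
  m <- fitPLS(X, y, 6)
  expect_equal(predict(m, X, preprocessed = TRUE), ols_predict(X, y),
               tolerance = 1e-8)
  # zero coefficients predict the training mean
  m@coefficients[] <- 0
  expect_equal(predict(m, X, preprocessed = TRUE), rep(mean(y), 20))
  # sample-order invariance
  m2 <- fitPLS(X, y, 3)
  perm <- sample(20)
  expect_equal(predict(m2, X, preprocessed = TRUE)[perm],
               predict(m2, X[perm, ], preprocessed = TRUE))
})

test_that("noise-free synthetic data is fit exactly at the generative rank", {
  d <- generateDataset(noise_free_config())
  X <- absorbance(d$spectra)
  k <- length(defaultComponents())   # generative component count
  for (p in monitoredProperties()) {
    m <- fitPLS(X, d$reference[[p]], k)
    expect_lt(rmse(d$reference[[p]], predict(m, X, preprocessed = TRUE)),
              1e-6)
  }
})
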