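test_that("interval bounds reproduce the standard equal-width partitions", {
  nu <- gridSeq(wavenumberGrid())
  iv20 <- makeIntervals(nu, 20, c(4000, 10000))
  expect_equal(unname(iv20$bounds[1, ]), c(4000, 4300))
  expect_equal(unname(iv20$bounds[2, ]), c(4300, 4600))
  iv10 <- makeIntervals(nu, 10, c(4000, 10000))
  expect_equal(unname(iv10$bounds[1, ]), c(4000, 4600))
  expect_equal(unname(iv10$bounds[5, ]), c(6400, 7000))
  iv15 <- makeIntervals(nu, 15, c(4000, 10000))
  expect_equal(unname(iv15$bounds[1, 2] - iv15$bounds[1, 1]), 400)
})

test_that("intervals partition the in-range grid points exactly", {
  nu <- gridSeq(wavenumberGrid())
  for (k in c(10, 15, 20, 25, 30)) {
    iv <- makeIntervals(nu, k, c(4000, 10000))
    all_idx <- sort(unlist(iv$indices))
    expect_identical(all_idx, which(nu >= 4000 & nu <= 10000))
    expect_identical(anyDuplicated(unlist(iv$indices)), 0L)
  }
  expect_error(makeIntervals(nu, 2000, c(4000, 10000)), "exceeds")
  expect_error(makeIntervals(nu, 10, c(3000, 10000)), "within the grid")
})

test_that("the search finds the interval that carries the signal", {
  set.seed(50)
  nu <- gridSeq(wavenumberGrid())
  n <- 40
  conc <- runif(n)
  # all signal inside interval 3 of 10 = [5200, 5800)
  sig <- exp(-(nu - 5350)^2 / (2 * 50^2)) + 0.6 * exp(-(nu - 5650)^2 / (2 * 60^2))
  X <- outer(conc, sig) + matrix(rnorm(n * length(nu), 0, 5e-3), n)
  si <- siplsSearch(X, conc, nu, intervalCounts = 10, comboSizes = 2,
                    maxLV = 4)
  lb <- leaderboard(si)
  top <- head(lb, 5)
  hasSignal <- vapply(strsplit(top$combination, "+", fixed = TRUE),
                      function(cc) "3" %in% cc, logical(1))
  expect_true(all(hasSignal))
  expect_true(3L %in% si@bestCombination)
  # confined signal: interval model beats full-spectrum PLS in CV error
  cvFull <- loocvRMSECV(X, conc, 4)
  expect_lte(si@rmsecv, cvFull$rmsecv_by_k[cvFull$chosen_k])
})

test_that("leaderboard enumerates the full search space, sorted", {
  set.seed(51)
  X <- matrix(rnorm(15 * 101), 15)
  nu <- seq(4000, 4800, by = 8)
  y <- rnorm(15)
  si <- siplsSearch(X, y, nu, intervalCounts = c(4, 6), comboSizes = c(2, 3),
                    maxLV = 2, sourceRange = c(4000, 4800))
  expect_equal(nrow(leaderboard(si)),
               choose(4, 2) + choose(4, 3) + choose(6, 2) + choose(6, 3))
  expect_false(is.unsorted(leaderboard(si)$rmsecv))
  expect_equal(leaderboard(si)$rmsecv[1], si@rmsecv)
})

test_that("search equals an independently coded exhaustive enumeration", {
  set.seed(52)
  n <- 14
  nu <- seq(4000, 4472, by = 8)          # 60 points, 6 intervals of 10
  t1 <- rnorm(n)
  X <- outer(t1, exp(-(nu - 4240)^2 / (2 * 30^2))) +
    matrix(rnorm(n * length(nu), 0, 0.01), n)
  y <- t1 + rnorm(n, 0, 0.05)
  si <- siplsSearch(X, y, nu, intervalCounts = 6, comboSizes = 2, maxLV = 3,
                    sourceRange = c(4000, 4472))
  # oracle: nested loops over combinations, plain-R PLS double-loop CV
  bounds <- 4000 + (4472 - 4000) / 6 * (0:6)
  best <- Inf; bestCombo <- NULL
  combos <- list()
  for (i in 1:5) for (j in (i + 1):6) {
    cols <- which((nu >= bounds[i] & nu < bounds[i + 1]) |
                  (nu >= bounds[j] & (nu < bounds[j + 1] | j == 6 & nu <= 4472)))
    rms <- loocv_oracle_pls(X[, cols, drop = FALSE], y, 3)
    combos[[paste(i, j)]] <- min(rms)
    if (min(rms) < best) { best <- min(rms); bestCombo <- c(i, j) }
  }
  expect_identical(si@bestCombination, as.integer(bestCombo))
  expect_lt(abs(si@rmsecv - best), 1e-10)
  # every enumerated RMSECV agrees with the oracle
  lb <- leaderboard(si)
  key <- gsub("+", " ", lb$combination, fixed = TRUE)
  expect_lt(max(abs(lb$rmsecv - unlist(combos)[key])), 1e-10)
})

test_that("results do not depend on the enumeration order of combinations", {
  set.seed(53)
  nu <- seq(4000, 4472, by = 8)
  X <- matrix(rnorm(12 * length(nu)), 12)
  y <- rnorm(12)
  a <- siplsSearch(X, y, nu, intervalCounts = c(4, 6), comboSizes = 2,
                   maxLV = 2, sourceRange = c(4000, 4472))
  b <- siplsSearch(X, y, nu, intervalCounts = c(6, 4), comboSizes = 2,
                   maxLV = 2, sourceRange = c(4000, 4472))
  expect_equal(a@rmsecv, b@rmsecv)
  expect_identical(a@bestCombination, b@bestCombination)
  expect_identical(a@bestK, b@bestK)
})
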