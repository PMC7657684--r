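test_that("spectra CSV round trip is lossless at full precision", {
  s <- random_spectra(n = 4, seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  writeSpectraCSV(s, f)
  s2 <- readSpectraCSV(f)
  expect_identical(absorbance(s2), absorbance(s))
  expect_identical(sampleId(s2), sampleId(s))
  expect_identical(batchId(s2), batchId(s))
  expect_identical(steamTime(s2), steamTime(s))
  expect_identical(wavenumbers(s2), wavenumbers(s))
})

test_that("non-uniform or descending wavenumber headers are rejected", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,batch_id,steam_time_s,4000,4008,4020",
               "a,b1,0,0.1,0.2,0.3"), f)
  expect_error(readSpectraCSV(f), "grid error")
  writeLines(c("sample_id,batch_id,steam_time_s,4016,4008,4000",
               "a,b1,0,0.1,0.2,0.3"), f)
  expect_error(readSpectraCSV(f), "ascending")
})

test_that("non-numeric absorbance cells are reported with row and column", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,batch_id,steam_time_s,4000,4008,4016",
               "a,b1,0,0.1,oops,0.3",
               "b,b1,30,0.1,0.2,0.3"), f)
  expect_error(readSpectraCSV(f), "row 1.*4008")
})

test_that("default-grid spectra files parse to 1001 points", {
  nu <- gridSeq(wavenumberGrid())
  expect_length(nu, 1001L)
  s <- SpectraSet(matrix(0.5, 3, 1001), nu)
  f <- withr::local_tempfile(fileext = ".csv")
  writeSpectraCSV(s, f)
  expect_equal(length(wavenumbers(readSpectraCSV(f))), 1001L)
})

test_that("reference CSV round trips, preserves row order, validates bounds", {
  d <- generateDataset(syntheticConfig(nBatches = 2, duration = 90, seed = 2))
  f <- withr::local_tempfile(fileext = ".csv")
  writeReferenceCSV(d$reference, f)
  r2 <- readReferenceCSV(f)
  expect_equal(r2, d$reference)
  expect_identical(r2$sample_id, d$reference$sample_id)

  bad <- d$reference
  bad$moisture[1] <- 120
  writeLines(capture.output(write.csv(bad, stdout(), row.names = FALSE)), f)
  expect_error(readReferenceCSV(f), "moisture")

  bad <- d$reference
  bad$gastrodin[2] <- -0.1
  writeLines(capture.output(write.csv(bad, stdout(), row.names = FALSE)), f)
  expect_error(readReferenceCSV(f), "negative")

  extra <- cbind(d$reference, note = "x")
  writeLines(capture.output(write.csv(extra, stdout(), row.names = FALSE)), f)
  expect_warning(r3 <- readReferenceCSV(f), "unknown")
  expect_named(r3, c("sample_id", monitoredProperties()))
})

test_that("model save/load round trip predicts bit-identically", {
  d <- generateDataset(syntheticConfig(nBatches = 2, duration = 150, seed = 4))
  ch <- fitChain(parseChain("MSC+SG9+FD"), d$spectra)
  X <- absorbance(applyChain(ch, d$spectra))
  m <- fitPLS(X, d$reference$gastrodin, 4, property = "gastrodin",
              wavenumbers = wavenumbers(d$spectra), preprocess = ch)
  f <- withr::local_tempfile(fileext = ".json")
  saveModel(m, f)
  m2 <- loadModel(f)
  expect_identical(predict(m2, d$spectra), predict(m, d$spectra))
  expect_identical(m2@method, m@method)
  expect_identical(m2@selectedVariables, m@selectedVariables)
})

test_that("model files with wrong version or truncation refuse to load", {
  m <- fitPLS(matrix(rnorm(40), 10), rnorm(10), 2)
  f <- withr::local_tempfile(fileext = ".json")
  saveModel(m, f)
  doc <- jsonlite::read_json(f)
  doc$version <- "0.0"
  jsonlite::write_json(doc, f, auto_unbox = TRUE)
  expect_error(loadModel(f), "version")
  writeLines(substr(paste(readLines(f), collapse = ""), 1, 50), f)
  expect_error(loadModel(f), "load error|version|readable")
})

test_that("a synergy-interval model stores its interval bounds in cm-1", {
  set.seed(10)
  nu <- gridSeq(wavenumberGrid())
  n <- 24
  conc <- runif(n)
  sig <- exp(-(nu - 4150)^2 / (2 * 60^2))
  X <- outer(conc, sig) + matrix(rnorm(n * length(nu), 0, 1e-3), n)
  si <- siplsSearch(X, conc, nu, intervalCounts = 20, comboSizes = 2,
                    maxLV = 3)
  expect_equal(unname(si@bestBounds[, 2] - si@bestBounds[, 1]), c(300, 300))
  f <- withr::local_tempfile(fileext = ".json")
  saveModel(bestModel(si), f)
  doc <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_true(all(doc$selected_wavenumbers >= 4000 &
                  doc$selected_wavenumbers <= 10000))
  expect_identical(doc$meta$interval_count, 20L)
})
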