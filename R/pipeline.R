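#' @include AllClasses.R synthetic-data.R preprocessing.R sample-selection.R
#' @include calibration.R interval-pls.R evaluation.R spectra-io.R
NULL

#' Default per-property preprocessing chains
#'
#' The chains that performed best per property in calibration screening of
#' this workflow family: `MSC+SG9+FD` for gastrodin and parishin A,
#' `MSC+SG7+FD` for p-hydroxybenzyl alcohol and parishin B, and `MSC+SG9+SD`
#' for moisture.
#' @return named character vector of chain labels
#' @export
defaultChains <- function() {
  c(gastrodin = "MSC+SG9+FD",
    p_hydroxybenzyl_alcohol = "MSC+SG7+FD",
    parishin_b = "MSC+SG7+FD",
    parishin_a = "MSC+SG9+FD",
    moisture = "MSC+SG9+SD")
}

#' Si-PLS search settings
#'
#' Defaults keep the exhaustive search desk-scale: interval counts
#' `{10, 15, 20}` over 4,000-10,000 cm-1, combinations of 2 or 3
#' subintervals, up to 12 latent variables (the same cap as the full-spectrum
#' models, so the comparison between them is fair). The wider count grid
#' `{10, 15, 20, 25, 30}` is available through these settings at
#' correspondingly higher cost.
#'
#' @param intervalCounts interval counts searched
#' @param comboSizes combination sizes searched
#' @param maxLV largest latent-variable count in the inner cross-validation
#' @param sourceRange spectral range searched (cm-1)
#' @export
siplsControl <- function(intervalCounts = c(10L, 15L, 20L),
                         comboSizes = c(2L, 3L),
                         maxLV = 12L, sourceRange = c(4000, 10000)) {
  list(intervalCounts = as.integer(intervalCounts),
       comboSizes = as.integer(comboSizes), maxLV = as.integer(maxLV),
       sourceRange = sourceRange)
}

#' End-to-end pipeline configuration
#'
#' @param simulate a [syntheticConfig()] used to generate the data, or `NULL`
#'   when `spectra`/`reference` supply measured data
#' @param spectra,reference a [SpectraSet-class] and matching reference
#'   data.frame (ignored when `simulate` is given)
#' @param chains named chain labels per property, see [defaultChains()]
#' @param sipls Si-PLS settings, see [siplsControl()]
#' @param calFraction fraction of retained samples assigned to calibration by
#'   Kennard-Stone
#' @param outlierPCs,outlierSd PCA outlier-screening settings
#' @param maxLV latent-variable search limit for full-PLS and PCR
#' @param smlr list of SMLR settings (`fEnter`, `fRemove`, `maxTerms`)
#' @param pcrRange wavenumber window (cm-1) the moisture PCR model is built
#'   on; the default is the full acquisition range, since the moisture signal
#'   after scatter correction lives in the contrast between the water O-H
#'   bands and the dry-matter background across the spectrum
#' @param seed integer seed for the whole run
#' @export
pipelineConfig <- function(simulate = syntheticConfig(),
                           spectra = NULL, reference = NULL,
                           chains = defaultChains(),
                           sipls = siplsControl(),
                           calFraction = 0.8,
                           outlierPCs = 3L, outlierSd = 3,
                           maxLV = 12L,
                           smlr = list(fEnter = 4.0, fRemove = 3.9,
                                       maxTerms = 10L),
                           pcrRange = c(4000, 12000),
                           seed = 1L) {
  if (is.null(simulate) && (is.null(spectra) || is.null(reference)))
    stop("either a simulate config or spectra + reference must be given")
  stopifnot(calFraction > 0, calFraction < 1)
  miss <- setdiff(PROPERTIES, names(chains))
  if (length(miss)) stop("chains missing for: ", paste(miss, collapse = ", "))
  structure(list(simulate = simulate, spectra = spectra,
                 reference = reference, chains = chains, sipls = sipls,
                 calFraction = calFraction, outlierPCs = as.integer(outlierPCs),
                 outlierSd = outlierSd, maxLV = as.integer(maxLV),
                 smlr = smlr, pcrRange = pcrRange, seed = as.integer(seed)),
            class = "pipelineConfig")
}

# model one property end to end; returns models, reports, split, outliers
run_property <- function(property, spectra, reference, config) {
  chain <- parseChain(config$chains[[property]])
  y_all <- reference[[property]][match(sampleId(spectra),
                                       reference$sample_id)]
  if (anyNA(y_all)) stop("reference table does not cover all spectra")
  # screening view: chain fitted on all samples, used only to pick outliers
  # and the split; modelling chains are refitted on calibration data below
  screenX <- chainFitApply(chain, spectra, spectra)$target
  out <- scoreOutliers(pcaScores(screenX, config$outlierPCs)$scores,
                       config$outlierSd)
  keep <- setdiff(seq_len(ncol(spectra)), out@flagged)
  kept <- spectra[, keep]
  screenKept <- absorbance(screenX)[keep, , drop = FALSE]
  nCal <- round(config$calFraction * length(keep))
  split <- kennardStone(screenKept, nCal)
  calS <- kept[, split@calibration]
  valS <- kept[, split@validation]
  yCal <- y_all[keep][split@calibration]
  yVal <- y_all[keep][split@validation]
  # honest preprocessing: fit on calibration only
  fitted <- chainFitApply(chain, calS, calS)
  fchain <- fitted$chain
  Xcal <- absorbance(fitted$target)
  nu <- wavenumbers(spectra)
  models <- list()
  if (property == "moisture") {
    # PCR on the moisture-related spectral area (the water O-H band window),
    # with Mahalanobis screening in the regression score space
    sel <- which(nu >= config$pcrRange[1] & nu <= config$pcrRange[2])
    mout <- mahalanobisOutliers(Xcal[, sel, drop = FALSE],
                                config$outlierPCs, config$outlierSd)
    if (length(mout@flagged)) {
      calS <- calS[, -mout@flagged]
      yCal <- yCal[-mout@flagged]
      fitted <- chainFitApply(chain, calS, calS)
      fchain <- fitted$chain
      Xcal <- absorbance(fitted$target)
    }
    cv <- loocvRMSECV(Xcal[, sel, drop = FALSE], yCal, config$maxLV,
                      method = "pcr")
    models$PCR <- fitPCR(Xcal[, sel, drop = FALSE], yCal, cv$chosen_k,
                         property = property, wavenumbers = nu,
                         selected = sel, preprocess = fchain,
                         cv = cv[c("rmsecv_by_k", "chosen_k")])
    pcrOutliers <- mout
  } else {
    models$SMLR <- fitSMLR(Xcal, yCal, config$smlr$fEnter, config$smlr$fRemove,
                           config$smlr$maxTerms, property = property,
                           wavenumbers = nu, preprocess = fchain)
    cv <- loocvRMSECV(Xcal, yCal, config$maxLV, method = "pls")
    models$PLS <- fitPLS(Xcal, yCal, cv$chosen_k, property = property,
                         wavenumbers = nu, preprocess = fchain,
                         cv = cv[c("rmsecv_by_k", "chosen_k")])
    si <- siplsSearch(Xcal, yCal, nu,
                      intervalCounts = config$sipls$intervalCounts,
                      comboSizes = config$sipls$comboSizes,
                      maxLV = config$sipls$maxLV,
                      sourceRange = config$sipls$sourceRange,
                      property = property, preprocess = fchain)
    models$SiPLS <- bestModel(si)
    pcrOutliers <- NULL
  }
  reports <- lapply(models, modelReport, calSpectra = calS, calY = yCal,
                    valSpectra = valS, valY = yVal)
  list(property = property, models = models, reports = reports,
       split = split, outliers = out,
       pcrOutliers = if (property == "moisture") pcrOutliers else NULL,
       sipls = if (property != "moisture") si else NULL,
       nRetained = length(keep))
}

#' Run the full monitoring workflow
#'
#' Per property: preprocess with the configured chain, screen spectral
#' outliers (PCA scores, Mahalanobis distance), split with Kennard-Stone,
#' fit the calibration models (SMLR, full-PLS and Si-PLS for the analytes;
#' Mahalanobis-screened PCR for moisture) and evaluate the full
#' performance-index panel on calibration and validation sets. Fully
#' reproducible from the configuration and its seed.
#'
#' @param config a [pipelineConfig()]
#' @param outDir optional directory; when given, models (JSON), reports and
#'   leaderboards (CSV), and a provenance log (config hash + seed) are written
#' @return list: `results` (per property), `comparison` (per-method table),
#'   `best` (best-model table: Si-PLS for analytes, PCR for moisture),
#'   `data` (the dataset used), `config`
#' @export
runPipeline <- function(config, outDir = NULL) {
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    sim$seed <- config$seed
    data <- generateDataset(sim)
  } else {
    data <- list(spectra = config$spectra, reference = config$reference,
                 truth = NULL)
  }
  results <- lapply(PROPERTIES, run_property, spectra = data$spectra,
                    reference = data$reference, config = config)
  names(results) <- PROPERTIES
  comparison <- do.call(rbind, unlist(lapply(results, function(r)
    lapply(r$reports, as.data.frame)), recursive = FALSE))
  rownames(comparison) <- NULL
  best <- do.call(rbind, lapply(results, function(r) {
    m <- if (r$property == "moisture") "PCR" else "SiPLS"
    as.data.frame(r$reports[[m]])
  }))
  rownames(best) <- NULL
  out <- list(results = results, comparison = comparison, best = best,
              data = data, config = config)
  if (!is.null(outDir)) writeRunDir(out, outDir)
  out
}

# provenance hash of the configuration (md5 of its canonical JSON)
configHash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  cfg <- config
  cfg$spectra <- NULL                    # large objects: hash settings only
  jsonlite::write_json(cfg, f, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(f))
}

writeRunDir <- function(run, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  hash <- configHash(run$config)
  # no timestamps anywhere: identical config + seed gives byte-identical output
  prov <- list(config_hash = hash, seed = run$config$seed)
  for (p in names(run$results)) {
    r <- run$results[[p]]
    for (m in names(r$models)) {
      r$models[[m]]@meta <- c(r$models[[m]]@meta, prov)
      saveModel(r$models[[m]], file.path(outDir,
                                         sprintf("model_%s_%s.json", p, m)))
    }
    if (!is.null(r$sipls))
      write.csv(cbind(leaderboard(r$sipls),
                      config_hash = hash, seed = run$config$seed),
                file.path(outDir, sprintf("leaderboard_%s.csv", p)),
                row.names = FALSE)
  }
  write.csv(cbind(run$comparison, config_hash = hash, seed = run$config$seed),
            file.path(outDir, "comparison.csv"), row.names = FALSE)
  write.csv(cbind(run$best, config_hash = hash, seed = run$config$seed),
            file.path(outDir, "best_models.csv"), row.names = FALSE)
  jsonlite::write_json(prov, file.path(outDir, "provenance.json"),
                       auto_unbox = TRUE)
  invisible(outDir)
}

#' Monitor a stream of process spectra with fitted models
#'
#' Emits one record per incoming spectrum (in the given order; a warning is
#' issued if steaming times are out of order) with the predictions of every
#' supplied model. When a paired reference table is given, per-property
#' paired t and variance F agreement tests between predictions and reference
#' values are appended.
#'
#' @param models named list of [CalibrationModel-class] objects (name =
#'   property), all trained on the stream's grid
#' @param stream a [SpectraSet-class] of incoming spectra
#' @param reference optional reference data.frame with `sample_id` and
#'   property columns
#' @return list: `records` (data.frame, one row per spectrum in time order)
#'   and `agreement` (data.frame of test results, or `NULL`)
#' @export
monitorProcess <- function(models, stream, reference = NULL) {
  if (ncol(stream) == 0)
    return(list(records = data.frame(sample_id = character(),
                                     steam_time_s = numeric()),
                agreement = NULL))
  tt <- steamTime(stream)
  # time restarts between batches are normal; flag disorder within a batch
  disorder <- vapply(split(tt, batchId(stream)), is.unsorted, logical(1))
  if (any(disorder))
    warning("monitor: steam times out of order; processing in given order")
  records <- data.frame(sample_id = sampleId(stream), steam_time_s = tt,
                        stringsAsFactors = FALSE)
  for (p in names(models))
    records[[p]] <- predict(models[[p]], stream)
  agreement <- NULL
  if (!is.null(reference)) {
    idx <- match(records$sample_id, reference$sample_id)
    if (anyNA(idx)) stop("reference table does not cover the stream")
    agreement <- do.call(rbind, lapply(names(models), function(p) {
      tt <- pairedTTest(reference[[p]][idx], records[[p]])
      ft <- varianceFTest(reference[[p]][idx], records[[p]])
      data.frame(property = p, t_statistic = tt$statistic,
                 t_p_value = tt$p_value, f_statistic = ft$statistic,
                 f_p_value = ft$p_value, n = tt$n,
                 stringsAsFactors = FALSE)
    }))
  }
  list(records = records, agreement = agreement)
}
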