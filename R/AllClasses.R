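#' @include AllGenerics.R
#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats var sd cor predict mahalanobis qchisq prcomp pf pt
#' @importFrom utils read.csv write.csv head
NULL

# ---------------------------------------------------------------------------
# WavenumberGrid
# ---------------------------------------------------------------------------

#' Uniform wavenumber grid
#'
#' Describes the spectral axis: a strictly ascending, uniformly spaced grid of
#' wavenumbers in cm-1. The default corresponds to FT-NIR diffuse-reflectance
#' acquisition from 4,000 to 12,000 cm-1 at 8 cm-1 resolution (1,001 points).
#'
#' @slot start first wavenumber (cm-1)
#' @slot end last wavenumber (cm-1)
#' @slot step grid spacing (cm-1)
#' @slot points number of grid points; always `(end - start)/step + 1`
#' @export
setClass("WavenumberGrid",
  representation(start = "numeric", end = "numeric", step = "numeric",
                 points = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@step <= 0) msg <- c(msg, "step must be positive")
    if (object@end <= object@start)
      msg <- c(msg, "grid must be strictly ascending (end > start)")
    np <- (object@end - object@start) / object@step + 1
    if (abs(np - round(np)) > 1e-8 || object@points != round(np))
      msg <- c(msg, "points must equal (end - start)/step + 1 exactly")
    if (length(msg)) msg else TRUE
  })

#' Construct a wavenumber grid
#'
#' @param start,end,step grid limits and spacing in cm-1
#' @return a [WavenumberGrid-class] object
#' @examples
#' g <- wavenumberGrid()          # 4,000-12,000 cm-1, step 8: 1,001 points
#' g@points
#' @export
wavenumberGrid <- function(start = 4000, end = 12000, step = 8) {
  np <- (end - start) / step + 1
  if (abs(np - round(np)) > 1e-8)
    stop("grid error: (end - start) is not a multiple of step")
  new("WavenumberGrid", start = start, end = end, step = step,
      points = as.integer(round(np)))
}

#' Wavenumber vector of a grid
#' @param g a WavenumberGrid
#' @return numeric vector of wavenumbers (cm-1), ascending
#' @export
gridSeq <- function(g) seq(g@start, g@end, by = g@step)

#' Infer a grid from a wavenumber vector
#'
#' Validates that the vector is strictly ascending with a uniform step.
#' @param nu numeric vector of wavenumbers (cm-1)
#' @export
gridFromWavenumbers <- function(nu) {
  if (length(nu) < 2) stop("grid error: need at least two wavenumbers")
  d <- diff(nu)
  if (any(d <= 0)) stop("grid error: wavenumbers must be strictly ascending")
  if (max(abs(d - d[1])) > 1e-6 * d[1])
    stop(sprintf("grid error: non-uniform step (%.6g then %.6g at position %d)",
                 d[1], d[which.max(abs(d - d[1]))],
                 which.max(abs(d - d[1])) + 1L))
  wavenumberGrid(nu[1], nu[length(nu)], d[1])
}

# ---------------------------------------------------------------------------
# SpectraSet
# ---------------------------------------------------------------------------

#' Set of NIR spectra with sample annotations
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding
#' one `absorbance` assay (wavenumbers as rows, samples as columns; values are
#' log(1/R) absorbance units) together with per-sample annotations
#' `sample_id`, `batch_id` and `steam_time_s`. The wavenumber grid is stored
#' in `rowData` and validated to be uniform and ascending.
#'
#' Most modelling functions consume [absorbance()], which returns the matrix
#' in the chemometric orientation (samples x wavenumbers).
#'
#' @export
setClass("SpectraSet", contains = "SummarizedExperiment",
  validity = function(object) {
    msg <- character()
    a <- SummarizedExperiment::assayNames(object)
    if (!identical(a, "absorbance"))
      msg <- c(msg, "assay must be a single 'absorbance' matrix")
    cd <- SummarizedExperiment::colData(object)
    need <- c("sample_id", "batch_id", "steam_time_s")
    if (!all(need %in% colnames(cd)))
      msg <- c(msg, paste("colData must contain", paste(need, collapse = ", ")))
    if (!all(is.finite(SummarizedExperiment::assay(object))))
      msg <- c(msg, "all absorbance values must be finite")
    nu <- SummarizedExperiment::rowData(object)$wavenumber
    if (is.null(nu)) {
      msg <- c(msg, "rowData must contain a 'wavenumber' column")
    } else {
      ok <- tryCatch({ gridFromWavenumbers(nu); TRUE },
                     error = function(e) conditionMessage(e))
      if (!isTRUE(ok)) msg <- c(msg, ok)
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a SpectraSet
#'
#' @param absorbance numeric matrix, samples in rows and wavenumbers in
#'   columns (log(1/R) absorbance units)
#' @param wavenumbers ascending, uniformly spaced wavenumber vector (cm-1);
#'   length must match `ncol(absorbance)`
#' @param sampleId,batchId character annotations, one per sample
#' @param steamTime steaming time in seconds, one per sample
#' @return a [SpectraSet-class]
#' @examples
#' nu <- gridSeq(wavenumberGrid())
#' x <- matrix(rnorm(3 * length(nu)), 3)
#' s <- SpectraSet(x, nu, sampleId = paste0("s", 1:3),
#'                 batchId = rep("b1", 3), steamTime = c(0, 30, 60))
#' dim(absorbance(s))
#' @export
SpectraSet <- function(absorbance, wavenumbers,
                       sampleId = paste0("s", seq_len(nrow(absorbance))),
                       batchId = rep("b1", nrow(absorbance)),
                       steamTime = rep(0, nrow(absorbance))) {
  absorbance <- as.matrix(absorbance)
  if (ncol(absorbance) != length(wavenumbers))
    stop("ncol(absorbance) must equal length(wavenumbers)")
  n <- nrow(absorbance)
  if (length(sampleId) != n || length(batchId) != n || length(steamTime) != n)
    stop("annotation lengths must equal the number of spectra (rows)")
  gridFromWavenumbers(wavenumbers)   # validates
  a <- t(absorbance)
  dimnames(a) <- NULL
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(absorbance = a),
    rowData = S4Vectors::DataFrame(wavenumber = as.numeric(wavenumbers)),
    colData = S4Vectors::DataFrame(sample_id = as.character(sampleId),
                                   batch_id = as.character(batchId),
                                   steam_time_s = as.numeric(steamTime),
                                   row.names = make.unique(as.character(sampleId))))
  new("SpectraSet", se)
}

#' @describeIn SpectraSet absorbance matrix, samples x wavenumbers
#' @param x a SpectraSet
#' @export
setMethod("absorbance", "SpectraSet", function(x, ...) {
  m <- t(SummarizedExperiment::assay(x, "absorbance"))
  rownames(m) <- sampleId(x)
  colnames(m) <- wavenumbers(x)
  m
})

#' @describeIn SpectraSet wavenumber vector (cm-1)
#' @export
setMethod("wavenumbers", "SpectraSet", function(x, ...)
  as.numeric(SummarizedExperiment::rowData(x)$wavenumber))

#' @describeIn SpectraSet sample identifiers
#' @export
setMethod("sampleId", "SpectraSet", function(x, ...)
  as.character(SummarizedExperiment::colData(x)$sample_id))

#' @describeIn SpectraSet batch identifiers
#' @export
setMethod("batchId", "SpectraSet", function(x, ...)
  as.character(SummarizedExperiment::colData(x)$batch_id))

#' @describeIn SpectraSet steaming time (seconds)
#' @export
setMethod("steamTime", "SpectraSet", function(x, ...)
  as.numeric(SummarizedExperiment::colData(x)$steam_time_s))

# replace the absorbance matrix (samples x wavenumbers), keeping annotations
setAbsorbance <- function(x, m) {
  SummarizedExperiment::assay(x, "absorbance", withDimnames = FALSE) <- t(m)
  x
}

setMethod("show", "SpectraSet", function(object) {
  nu <- wavenumbers(object)
  cat(sprintf("SpectraSet: %d spectra x %d wavenumbers (%g-%g cm-1, step %g)\n",
              ncol(object), nrow(object), min(nu), max(nu), nu[2] - nu[1]))
  cat(sprintf("  batches: %s\n",
              paste(unique(batchId(object)), collapse = ", ")))
  tt <- steamTime(object)
  cat(sprintf("  steam time: %g-%g s\n", min(tt), max(tt)))
})

# ---------------------------------------------------------------------------
# Preprocessing steps and chains
# ---------------------------------------------------------------------------

#' @export
setClass("PreprocessStep", representation("VIRTUAL"))

#' Multiplicative scatter correction step
#'
#' Regresses each spectrum on a reference (the calibration-set mean) and
#' inverts the fitted affine distortion. Unfitted until [mscFit()] or
#' [fitChain()] stores the reference.
#' @slot reference fitted mean calibration spectrum (length 0 when unfitted)
#' @export
setClass("MSCStep", contains = "PreprocessStep",
         representation(reference = "numeric"),
         prototype(reference = numeric(0)))

#' Standard normal variate step (stateless)
#' @export
setClass("SNVStep", contains = "PreprocessStep")

#' Savitzky-Golay filtering/derivative step (stateless)
#' @slot window odd window length in points
#' @slot polyorder local polynomial order; must exceed `deriv` and be
#'   smaller than `window`
#' @slot deriv derivative order 0, 1 or 2; derivatives are returned per cm-1
#' @export
setClass("SGStep", contains = "PreprocessStep",
         representation(window = "integer", polyorder = "integer",
                        deriv = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@window %% 2L == 0L) msg <- c(msg, "SG window must be odd")
    if (object@polyorder >= object@window)
      msg <- c(msg, "SG polyorder must be smaller than the window")
    if (object@deriv > object@polyorder)
      msg <- c(msg, "SG deriv must not exceed polyorder")
    if (!object@deriv %in% 0:2) msg <- c(msg, "SG deriv must be 0, 1 or 2")
    if (length(msg)) msg else TRUE
  })

#' @rdname SGStep-class
#' @param window,polyorder,deriv see slots
#' @export
sgStep <- function(window = 9L, polyorder = 2L, deriv = 0L)
  new("SGStep", window = as.integer(window), polyorder = as.integer(polyorder),
      deriv = as.integer(deriv))

#' @rdname MSCStep-class
#' @export
mscStep <- function() new("MSCStep")

#' @rdname SNVStep-class
#' @export
snvStep <- function() new("SNVStep")

#' Ordered preprocessing chain
#'
#' Holds an ordered list of [PreprocessStep-class] objects with the
#' fit-on-calibration / apply-to-any contract: stateful steps (MSC) are fitted
#' on calibration spectra only, then applied unchanged to any spectra.
#' @slot steps list of PreprocessStep objects
#' @export
setClass("PreprocessChain", representation(steps = "list"),
  validity = function(object) {
    ok <- vapply(object@steps, is, logical(1), class2 = "PreprocessStep")
    if (all(ok)) TRUE else "all elements must be PreprocessStep objects"
  })

#' @rdname PreprocessChain-class
#' @param ... PreprocessStep objects, in application order
#' @export
preprocessChain <- function(...) new("PreprocessChain", steps = list(...))

setMethod("show", "PreprocessChain", function(object) {
  cat("PreprocessChain:", chainLabel(object), "\n")
})

# ---------------------------------------------------------------------------
# CalibrationModel
# ---------------------------------------------------------------------------

#' Fitted multivariate calibration model
#'
#' A linear calibration in the (preprocessed) spectral space:
#' `yhat = yMean + (x[selected] - xMean) %*% coefficients`. Covers SMLR,
#' full-spectrum PLS, synergy-interval PLS and PCR; the latent structure
#' used to obtain the coefficients is recorded in `nComponents` and `fit`.
#'
#' @slot method one of "SMLR", "PLS", "SiPLS", "PCR"
#' @slot property name of the modelled quantity (e.g. "gastrodin")
#' @slot nComponents latent variables (PLS/PCR) or selected-term count (SMLR)
#' @slot wavenumbers full training wavenumber grid (cm-1)
#' @slot selectedVariables column indices (into the grid) used by the model
#' @slot xMean training means of the selected (preprocessed) variables
#' @slot yMean training mean of the response
#' @slot coefficients regression coefficients over the selected variables
#' @slot preprocess the fitted [PreprocessChain-class]
#' @slot cv list with `rmsecv_by_k` and `chosen_k` when components were
#'   selected by cross-validation (may be empty)
#' @slot meta free-form training metadata (seed, data hash, metric snapshot)
#' @export
setClass("CalibrationModel",
  representation(method = "character", property = "character",
                 nComponents = "integer", wavenumbers = "numeric",
                 selectedVariables = "integer", xMean = "numeric",
                 yMean = "numeric", coefficients = "numeric",
                 preprocess = "PreprocessChain", cv = "list", meta = "list"),
  prototype(preprocess = new("PreprocessChain", steps = list()),
            cv = list(), meta = list()),
  validity = function(object) {
    msg <- character()
    if (!object@method %in% c("SMLR", "PLS", "SiPLS", "PCR"))
      msg <- c(msg, "unknown method tag")
    p <- length(object@selectedVariables)
    if (length(object@coefficients) != p)
      msg <- c(msg, "coefficient length must equal selected-variable count")
    if (length(object@xMean) != p)
      msg <- c(msg, "xMean length must equal selected-variable count")
    if (object@nComponents < 1L) msg <- c(msg, "nComponents must be >= 1")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "CalibrationModel", function(object) {
  cat(sprintf("CalibrationModel <%s> for %s: %d component(s), %d variable(s)\n",
              object@method, object@property, object@nComponents,
              length(object@selectedVariables)))
  if (length(object@cv))
    cat(sprintf("  RMSECV at chosen k: %.6g\n",
                object@cv$rmsecv_by_k[object@cv$chosen_k]))
})

# ---------------------------------------------------------------------------
# Reports and results
# ---------------------------------------------------------------------------

#' Performance-index report for one calibration model
#'
#' The standard NIR validation panel: calibration R2 and RMSEC, RMSECV,
#' prediction R2, RMSEP, RPD (validation SD / RMSEP) and RSEP (%).
#' @export
setClass("MetricsReport",
  representation(property = "character", method = "character",
                 rc2 = "numeric", rmsec = "numeric", rmsecv = "numeric",
                 rp2 = "numeric", rmsep = "numeric", rpd = "numeric",
                 rsep = "numeric", nComponents = "integer"))

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport [%s / %s]\n", object@property, object@method))
  print(as.data.frame(object))
})

#' @export
as.data.frame.MetricsReport <- function(x, ...) {
  data.frame(property = x@property, method = x@method, Rc2 = x@rc2,
             RMSEC = x@rmsec, RMSECV = x@rmsecv, Rp2 = x@rp2,
             RMSEP = x@rmsep, RPD = x@rpd, RSEP = x@rsep,
             LVs = x@nComponents, stringsAsFactors = FALSE)
}

#' Synergy-interval PLS search result
#'
#' @slot bestModel the winning [CalibrationModel-class]
#' @slot bestCombination interval indices of the winning combination
#' @slot bestBounds matrix (one row per interval) of low/high bounds in cm-1
#' @slot bestK the interval count the winner was drawn from
#' @slot rmsecv the winning cross-validated error
#' @slot leaderboard data.frame of every combination searched, sorted
#'   ascending by RMSECV
#' @export
setClass("SiplsResult",
  representation(bestModel = "CalibrationModel", bestCombination = "integer",
                 bestBounds = "matrix", bestK = "integer", rmsecv = "numeric",
                 leaderboard = "data.frame"),
  validity = function(object) {
    lb <- object@leaderboard
    if (nrow(lb) && is.unsorted(lb$rmsecv))
      "leaderboard must be sorted ascending by rmsecv" else TRUE
  })

#' @describeIn SiplsResult the winning model
#' @param x a SiplsResult
#' @export
setMethod("bestModel", "SiplsResult", function(x) x@bestModel)

#' @describeIn SiplsResult the full ranked search table
#' @export
setMethod("leaderboard", "SiplsResult", function(x) x@leaderboard)

setMethod("show", "SiplsResult", function(object) {
  cat(sprintf("SiplsResult: best RMSECV %.6g with %d interval(s) of %d (k=%d LVs)\n",
              object@rmsecv, length(object@bestCombination), object@bestK,
              object@bestModel@nComponents))
  b <- object@bestBounds
  cat("  intervals:",
      paste(sprintf("[%g, %g)", b[, 1], b[, 2]), collapse = " "), "cm-1\n")
})

#' Outlier screening report
#' @slot flagged indices of flagged samples
#' @slot statistic per-sample Mahalanobis distance in score space
#' @slot threshold distance threshold used
#' @slot kind statistic label
#' @export
setClass("OutlierReport",
  representation(flagged = "integer", statistic = "numeric",
                 threshold = "numeric", kind = "character"))

setMethod("show", "OutlierReport", function(object) {
  cat(sprintf("OutlierReport (%s): %d flagged at threshold %.3g\n",
              object@kind, length(object@flagged), object@threshold))
  if (length(object@flagged)) cat("  indices:", object@flagged, "\n")
})

#' Calibration/validation partition
#' @slot calibration,validation disjoint sample indices covering all samples
#' @export
setClass("SplitResult",
  representation(calibration = "integer", validation = "integer"),
  validity = function(object) {
    if (length(intersect(object@calibration, object@validation)))
      "calibration and validation indices must be disjoint" else TRUE
  })

setMethod("show", "SplitResult", function(object) {
  cat(sprintf("SplitResult: %d calibration / %d validation\n",
              length(object@calibration), length(object@validation)))
})
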