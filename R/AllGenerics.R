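NULL

#' @export
setGeneric("absorbance", function(x, ...) standardGeneric("absorbance"))

#' @export
setGeneric("wavenumbers", function(x, ...) standardGeneric("wavenumbers"))

#' @export
setGeneric("sampleId", function(x, ...) standardGeneric("sampleId"))

#' @export
setGeneric("batchId", function(x, ...) standardGeneric("batchId"))

#' @export
setGeneric("steamTime", function(x, ...) standardGeneric("steamTime"))

#' @export
setGeneric("fitStep", function(step, x, ...) standardGeneric("fitStep"))

#' @export
setGeneric("applyStep", function(step, x, ...) standardGeneric("applyStep"))

#' @export
setGeneric("isFitted", function(x) standardGeneric("isFitted"))

#' @export
setGeneric("fitChain", function(chain, calibration, ...)
  standardGeneric("fitChain"))

#' @export
setGeneric("applyChain", function(chain, x, ...)
  standardGeneric("applyChain"))

#' @export
setGeneric("snv", function(x, ...) standardGeneric("snv"))

#' @export
setGeneric("savgol", function(x, window = 9L, polyorder = 2L, deriv = 0L, ...)
  standardGeneric("savgol"))

#' @export
setGeneric("mscApply", function(step, x, ...) standardGeneric("mscApply"))

#' @export
setGeneric("bestModel", function(x) standardGeneric("bestModel"))

#' @export
setGeneric("leaderboard", function(x) standardGeneric("leaderboard"))
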