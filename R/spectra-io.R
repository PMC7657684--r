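#' @include AllClasses.R
NULL

MODEL_FORMAT_VERSION <- "1.0"

#' Read spectra from CSV
#'
#' Expected layout: columns `sample_id`, `batch_id`, `steam_time_s`, then one
#' column per wavenumber labelled with its cm-1 value, ascending with a
#' uniform step. Row order is preserved.
#'
#' @param path CSV file path
#' @return a [SpectraSet-class]
#' @seealso [writeSpectraCSV()]
#' @export
readSpectraCSV <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "batch_id", "steam_time_s")
  if (!identical(colnames(df)[1:3], need))
    stop("spectra CSV must start with columns sample_id, batch_id, steam_time_s")
  nu <- suppressWarnings(as.numeric(colnames(df)[-(1:3)]))
  if (anyNA(nu)) stop("grid error: non-numeric wavenumber header")
  gridFromWavenumbers(nu)
  m <- as.matrix(df[, -(1:3), drop = FALSE])
  if (!is.numeric(m) || anyNA(m)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -(1:3)], 2, as.numeric))),
                 arr.ind = TRUE)[1, ]
    stop(sprintf("parse error: non-numeric absorbance at row %d, column %s",
                 bad[1], colnames(df)[-(1:3)][bad[2]]))
  }
  SpectraSet(m, nu, sampleId = df$sample_id, batchId = df$batch_id,
             steamTime = df$steam_time_s)
}

#' Write spectra to CSV
#'
#' Full double precision is kept, so `readSpectraCSV(writeSpectraCSV(x))` is
#' an exact round trip.
#' @param spectra a [SpectraSet-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeSpectraCSV <- function(spectra, path) {
  m <- absorbance(spectra)
  df <- data.frame(sample_id = sampleId(spectra),
                   batch_id = batchId(spectra),
                   steam_time_s = steamTime(spectra),
                   stringsAsFactors = FALSE, check.names = FALSE)
  ab <- as.data.frame(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                      stringsAsFactors = FALSE)
  colnames(ab) <- wavenumbers(spectra)
  write.csv(cbind(df, ab), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a reference-value table from CSV
#'
#' Required columns: `sample_id` plus the five monitored properties
#' (`gastrodin`, `p_hydroxybenzyl_alcohol`, `parishin_b`, `parishin_a` in
#' % w/w, `moisture` in %). Unknown extra columns are dropped with a warning;
#' missing or negative values, or moisture above 100 %, are errors.
#'
#' @param path CSV file path
#' @return data.frame in file row order
#' @export
readReferenceCSV <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", PROPERTIES)
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("reference CSV is missing columns: ", paste(miss, collapse = ", "))
  extra <- setdiff(colnames(df), need)
  if (length(extra)) {
    warning("ignoring unknown reference columns: ",
            paste(extra, collapse = ", "))
    df <- df[, need]
  }
  df <- df[, need]
  validateReferenceTable(df)
  df
}

#' Validate a reference table
#' @param df data.frame with `sample_id` and the five property columns
#' @return `df`, invisibly, or an error
#' @export
validateReferenceTable <- function(df) {
  vals <- as.matrix(df[, PROPERTIES])
  if (anyNA(vals)) stop("validation error: missing reference value")
  if (any(vals < 0)) stop("validation error: negative reference value")
  if (any(df$moisture > 100))
    stop("validation error: moisture above 100 %")
  invisible(df)
}

#' Write a reference table to CSV
#' @param df reference data.frame
#' @param path output path
#' @return `path`, invisibly
#' @export
writeReferenceCSV <- function(df, path) {
  validateReferenceTable(df)
  out <- df
  for (nm in PROPERTIES)
    out[[nm]] <- format(df[[nm]], digits = 17, trim = TRUE, scientific = TRUE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# serialize a preprocessing chain to a plain list (and back)
chain_to_list <- function(chain) {
  lapply(chain@steps, function(s) {
    if (is(s, "MSCStep")) list(kind = "msc", reference = s@reference)
    else if (is(s, "SNVStep")) list(kind = "snv")
    else list(kind = "sg", window = s@window, polyorder = s@polyorder,
              deriv = s@deriv)
  })
}

chain_from_list <- function(lst) {
  steps <- lapply(lst, function(s) {
    switch(s$kind,
      msc = new("MSCStep", reference = as.numeric(s$reference)),
      snv = snvStep(),
      sg = sgStep(s$window, s$polyorder, s$deriv),
      stop("unknown step kind in model file"))
  })
  new("PreprocessChain", steps = steps)
}

#' Save a fitted calibration model as structured text
#'
#' Versioned JSON document carrying everything needed to reproduce
#' predictions bit-identically: method, fitted preprocessing chain, selected
#' variables, coefficients, centring constants and training metadata.
#'
#' @param model a [CalibrationModel-class]
#' @param path output path (.json)
#' @return `path`, invisibly
#' @export
saveModel <- function(model, path) {
  doc <- list(format = "steamchem-model", version = MODEL_FORMAT_VERSION,
              method = model@method, property = model@property,
              n_components = model@nComponents,
              wavenumbers = model@wavenumbers,
              selected_variables = model@selectedVariables,
              selected_wavenumbers = model@wavenumbers[model@selectedVariables],
              x_mean = model@xMean, y_mean = model@yMean,
              coefficients = model@coefficients,
              preprocess = chain_to_list(model@preprocess),
              cv = model@cv, meta = model@meta)
  # digits = I(17): decimal round trip of IEEE doubles is exact, so a loaded
  # model predicts bit-identically
  jsonlite::write_json(doc, path, digits = I(17), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Load a calibration model saved by [saveModel()]
#'
#' Refuses documents whose format-version field does not match the current
#' format.
#' @param path model file path
#' @return a [CalibrationModel-class]
#' @export
loadModel <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE,
                                      simplifyDataFrame = FALSE),
                  error = function(e)
                    stop("load error: not a readable model file: ",
                         conditionMessage(e), call. = FALSE))
  if (!identical(doc$format, "steamchem-model"))
    stop("load error: not a steamchem model file")
  if (!identical(doc$version, MODEL_FORMAT_VERSION))
    stop(sprintf("load error: model format version '%s' != supported '%s'",
                 doc$version, MODEL_FORMAT_VERSION))
  new("CalibrationModel", method = doc$method, property = doc$property,
      nComponents = as.integer(doc$n_components),
      wavenumbers = as.numeric(doc$wavenumbers),
      selectedVariables = as.integer(doc$selected_variables),
      xMean = as.numeric(doc$x_mean), yMean = as.numeric(doc$y_mean),
      coefficients = as.numeric(doc$coefficients),
      preprocess = chain_from_list(doc$preprocess),
      cv = if (is.null(doc$cv)) list() else doc$cv,
      meta = if (is.null(doc$meta)) list() else doc$meta)
}
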