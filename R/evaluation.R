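#' @include AllClasses.R
NULL

#' Root mean square error
#'
#' `sqrt(mean((yhat - y)^2))` — RMSEC, RMSECV or RMSEP depending on which set
#' the pairs come from.
#' @param y reference values
#' @param yhat predictions, same length
#' @export
rmse <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch between y and yhat")
  if (!length(y)) stop("empty vectors")
  sqrt(mean((yhat - y)^2))
}

#' Determination coefficient
#'
#' By NIR convention (the convention of the instrument-vendor chemometrics
#' software family) this is the squared Pearson correlation between reference
#' and predicted values; `method = "ss"` gives the sum-of-squares variant
#' `1 - SSres/SStot` instead. The two agree for least-squares fits on their
#' own calibration data and differ under affine miscalibration.
#'
#' @param y reference values (variance > 0)
#' @param yhat predictions (variance > 0 for the Pearson variant)
#' @param method `"pearson"` (default) or `"ss"`
#' @export
rSquared <- function(y, yhat, method = c("pearson", "ss")) {
  method <- match.arg(method)
  if (length(y) != length(yhat)) stop("length mismatch between y and yhat")
  if (var(y) <= 0) stop("zero variance in y")
  if (method == "pearson") {
    if (var(yhat) <= 0) stop("zero variance in yhat")
    cor(y, yhat)^2
  } else {
    1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  }
}

#' Residual predictive deviation
#'
#' Ratio of the validation set's reference standard deviation to the RMSEP;
#' values of 3 and above indicate a model usable for quantitative work.
#' @param validationSd standard deviation (n-1) of the validation references
#' @param rmsep root mean square error of prediction (> 0)
#' @export
rpd <- function(validationSd, rmsep) {
  if (rmsep <= 0) stop("rmsep must be > 0")
  validationSd / rmsep
}

#' Relative standard error of prediction (%)
#'
#' Root relative squared error: `100 * sqrt(sum((yhat - y)^2) / sum(y^2))`.
#' Scale-invariant.
#' @param y reference values (not all zero)
#' @param yhat predictions
#' @export
rsep <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch between y and yhat")
  if (sum(y^2) <= 0) stop("rsep undefined for an all-zero reference vector")
  100 * sqrt(sum((yhat - y)^2) / sum(y^2))
}

#' Paired t-test between two measurement methods
#'
#' Two-sided paired t-test on the per-sample differences, as used to compare
#' reference-assay and NIR-predicted contents.
#' @param a,b paired measurement vectors (equal length >= 2)
#' @return list: `statistic`, `p_value`, `test = "paired_t"`, `n`
#' @export
pairedTTest <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  if (length(a) < 2) stop("need at least two pairs")
  d <- a - b
  if (var(d) < .Machine$double.eps)
    if (all(d == 0)) {
      return(list(statistic = 0, p_value = 1, test = "paired_t",
                  n = length(a)))
    } else stop("zero variance in paired differences")
  ht <- stats::t.test(a, b, paired = TRUE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       test = "paired_t", n = length(a))
}

#' Two-sided F-test comparing two variances
#'
#' The statistic is the larger sample variance over the smaller, making the
#' result symmetric in the two inputs; the p-value is two-sided from the F
#' distribution with the matching degrees of freedom.
#' @param a,b measurement vectors (each length >= 2, nonzero variance)
#' @return list: `statistic`, `p_value`, `test = "variance_F"`, `n`
#' @export
varianceFTest <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("need at least two values per group")
  va <- var(a); vb <- var(b)
  if (va < .Machine$double.eps || vb < .Machine$double.eps)
    stop("zero variance in one of the groups")
  if (va >= vb) {
    f <- va / vb; df1 <- length(a) - 1L; df2 <- length(b) - 1L
  } else {
    f <- vb / va; df1 <- length(b) - 1L; df2 <- length(a) - 1L
  }
  p <- min(1, 2 * stats::pf(f, df1, df2, lower.tail = FALSE))
  if (va == vb) p <- 1   # equal variances, equal dfs: two-sided p is exactly 1
  list(statistic = f, p_value = p, test = "variance_F",
       n = c(length(a), length(b)))
}

#' Assemble the full performance-index report for one model
#'
#' Computes the calibration (Rc2, RMSEC), cross-validation (RMSECV, taken
#' from the component-selection record stored in the model) and validation
#' (Rp2, RMSEP, RPD, RSEP) indexes. Refuses overlapping calibration and
#' validation sample ids (leakage guard).
#'
#' @param model a fitted [CalibrationModel-class]
#' @param calSpectra,calY calibration spectra ([SpectraSet-class]) and
#'   reference values
#' @param valSpectra,valY validation spectra and reference values
#' @return a [MetricsReport-class]
#' @export
modelReport <- function(model, calSpectra, calY, valSpectra, valY) {
  if (is(calSpectra, "SpectraSet") && is(valSpectra, "SpectraSet")) {
    ov <- intersect(sampleId(calSpectra), sampleId(valSpectra))
    if (length(ov))
      stop("leakage guard: calibration and validation sets share sample ids: ",
           paste(head(ov, 3), collapse = ", "))
  }
  calHat <- predict(model, calSpectra)
  valHat <- predict(model, valSpectra)
  rmsecv <- if (length(model@cv) && !is.null(model@cv$rmsecv_by_k))
    as.numeric(model@cv$rmsecv_by_k[model@cv$chosen_k]) else NA_real_
  rmsep <- rmse(valY, valHat)
  new("MetricsReport", property = model@property, method = model@method,
      rc2 = rSquared(calY, calHat), rmsec = rmse(calY, calHat),
      rmsecv = rmsecv, rp2 = rSquared(valY, valHat), rmsep = rmsep,
      rpd = rpd(sd(valY), rmsep), rsep = rsep(valY, valHat),
      nComponents = model@nComponents)
}
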