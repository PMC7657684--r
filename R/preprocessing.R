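#' @include AllClasses.R AllGenerics.R
NULL

as_spectra_matrix <- function(x) {
  if (is(x, "SpectraSet")) absorbance(x) else as.matrix(x)
}

# wrap a matrix result back into the container the caller supplied
rewrap <- function(x, m) {
  if (is(x, "SpectraSet")) setAbsorbance(x, m) else m
}

# ---------------------------------------------------------------------------
# MSC
# ---------------------------------------------------------------------------

#' Fit multiplicative scatter correction
#'
#' Stores the mean calibration spectrum used as the MSC reference. The fit
#' uses calibration spectra only; the fitted step can then be applied to any
#' spectra on the same grid, including validation or monitoring data, without
#' information leakage.
#'
#' @param calibration a [SpectraSet-class] or samples-by-wavenumbers matrix
#'   with at least two spectra
#' @return a fitted [MSCStep-class]
#' @seealso [mscApply()], [preprocessChain()]
#' @export
mscFit <- function(calibration) {
  m <- as_spectra_matrix(calibration)
  if (nrow(m) < 2)
    stop("MSC requires at least two calibration spectra")
  new("MSCStep", reference = unname(colMeans(m)))
}

#' Apply a fitted MSC step
#'
#' Each spectrum `x` is regressed on the reference `m` as `x = a + b * m`
#' (ordinary least squares over wavenumbers) and corrected to `(x - a) / b`,
#' removing per-spectrum additive offset and multiplicative scatter gain.
#' Spectra with `|b| < 1e-12` cannot be corrected; they are returned
#' unchanged with a warning.
#'
#' @param step a fitted [MSCStep-class]
#' @param x spectra to correct (SpectraSet or matrix on the training grid)
#' @return corrected spectra, same container as the input
#' @export
setMethod("mscApply", "MSCStep", function(step, x, ...) {
  if (!length(step@reference)) stop("MSC step is not fitted")
  m <- as_spectra_matrix(x)
  if (ncol(m) != length(step@reference))
    stop("grid mismatch between MSC reference and spectra")
  ref <- step@reference
  refc <- ref - mean(ref)
  ss <- sum(refc^2)
  xbar <- rowMeans(m)
  b <- as.numeric((m %*% refc) - xbar * sum(refc)) / ss  # sum(refc)=0; kept for clarity
  a <- xbar - b * mean(ref)
  bad <- abs(b) < 1e-12
  out <- (m - a) / b
  if (any(bad)) {
    warning(sprintf("MSC: %d spectra with near-zero scatter gain left unchanged",
                    sum(bad)))
    out[bad, ] <- m[bad, , drop = FALSE]
  }
  rewrap(x, out)
})

# ---------------------------------------------------------------------------
# SNV
# ---------------------------------------------------------------------------

#' Standard normal variate transform
#'
#' Row-wise standardization: each spectrum is centred to mean 0 and scaled to
#' unit sample standard deviation (n-1 denominator).
#'
#' @param x a [SpectraSet-class] or samples-by-wavenumbers matrix
#' @return transformed spectra, same container as the input
#' @export
setMethod("snv", "ANY", function(x, ...) {
  m <- as_spectra_matrix(x)
  s <- apply(m, 1, sd)
  if (any(s < .Machine$double.eps * 100)) {
    i <- which(s < .Machine$double.eps * 100)[1]
    nm <- if (!is.null(rownames(m))) rownames(m)[i] else as.character(i)
    stop(sprintf("SNV: spectrum '%s' has zero variance", nm))
  }
  rewrap(x, (m - rowMeans(m)) / s)
})

# ---------------------------------------------------------------------------
# Savitzky-Golay
# ---------------------------------------------------------------------------

# weights of the local polynomial fit: value (or deriv-th derivative) at
# offset 0 of the least-squares polynomial of order `polyorder` through the
# points at integer offsets `off`
sg_weights <- function(off, polyorder, deriv) {
  D <- outer(off, 0:polyorder, `^`)
  Wp <- solve(crossprod(D), t(D))     # (p+1) x length(off)
  Wp[deriv + 1, ] * factorial(deriv)
}

#' Savitzky-Golay smoothing and derivatives
#'
#' Local least-squares polynomial filtering along the wavenumber axis.
#' Derivatives are scaled by the grid step, so `deriv = 1` returns
#' d(absorbance)/d(cm-1) regardless of resolution. Near the spectrum ends the
#' window is truncated to the available points and the local polynomial order
#' reduced when necessary, so the output keeps the full grid length.
#'
#' @param x a [SpectraSet-class] or samples-by-wavenumbers matrix
#' @param window odd window length in points (e.g. 7 or 9)
#' @param polyorder local polynomial order (< window)
#' @param deriv derivative order 0, 1 or 2 (<= polyorder)
#' @param step grid step in cm-1; taken from the SpectraSet when available
#' @return filtered spectra, same container as the input
#' @export
setMethod("savgol", "ANY",
  function(x, window = 9L, polyorder = 2L, deriv = 0L, step = NULL, ...) {
  m <- as_spectra_matrix(x)
  if (is.null(step))
    step <- if (is(x, "SpectraSet")) diff(wavenumbers(x)[1:2]) else 1
  st <- new("SGStep", window = as.integer(window),
            polyorder = as.integer(polyorder), deriv = as.integer(deriv))
  n <- ncol(m)
  if (st@window > n) stop("SG window exceeds the number of grid points")
  h <- (st@window - 1L) %/% 2L
  out <- matrix(0, nrow(m), n, dimnames = dimnames(m))
  # interior: shared convolution weights, applied as shifted-column sums
  w <- sg_weights(-h:h, st@polyorder, st@deriv)
  inner <- (h + 1L):(n - h)
  acc <- matrix(0, nrow(m), length(inner))
  for (k in seq_len(st@window))
    acc <- acc + w[k] * m[, (k - 1L) + seq_along(inner), drop = FALSE]
  out[, inner] <- acc
  # edges: truncated window, reduced order if needed
  edge <- function(i) {
    idx <- max(1L, i - h):min(n, i + h)
    q <- min(st@polyorder, length(idx) - 1L)
    if (q < st@deriv)
      stop("SG window too small to support the derivative at the spectrum edge")
    sg_weights(idx - i, q, st@deriv)
  }
  for (i in seq_len(h)) {
    out[, i] <- m[, 1L:(i + h), drop = FALSE] %*% edge(i)
    j <- n - i + 1L
    out[, j] <- m[, (j - h):n, drop = FALSE] %*% edge(j)
  }
  rewrap(x, out / step^st@deriv)
})

# ---------------------------------------------------------------------------
# Steps: fit/apply dispatch used by chains
# ---------------------------------------------------------------------------

setMethod("fitStep", "MSCStep", function(step, x, ...) mscFit(x))
setMethod("fitStep", "SNVStep", function(step, x, ...) step)
setMethod("fitStep", "SGStep", function(step, x, ...) step)

setMethod("applyStep", "MSCStep", function(step, x, ...) mscApply(step, x))
setMethod("applyStep", "SNVStep", function(step, x, ...) snv(x))
setMethod("applyStep", "SGStep", function(step, x, step_cm1 = 1, ...)
  savgol(x, step@window, step@polyorder, step@deriv, step = step_cm1))

setMethod("isFitted", "PreprocessChain", function(x)
  all(vapply(x@steps, function(s)
    !is(s, "MSCStep") || length(s@reference) > 0, logical(1))))

# ---------------------------------------------------------------------------
# Chains
# ---------------------------------------------------------------------------

#' Fit a preprocessing chain on calibration spectra
#'
#' Steps are fitted and applied in order: each stateful step sees the
#' calibration data as transformed by the preceding steps, exactly as it will
#' at application time.
#'
#' @param chain a [PreprocessChain-class]
#' @param calibration calibration spectra (SpectraSet or matrix)
#' @return the chain with all stateful steps fitted
#' @export
setMethod("fitChain", "PreprocessChain", function(chain, calibration, ...) {
  cur <- as_spectra_matrix(calibration)
  step_cm1 <- if (is(calibration, "SpectraSet"))
    diff(wavenumbers(calibration)[1:2]) else 1
  steps <- chain@steps
  for (i in seq_along(steps)) {
    steps[[i]] <- tryCatch(fitStep(steps[[i]], cur),
      error = function(e) stop(sprintf("chain step %d: %s", i,
                                       conditionMessage(e)), call. = FALSE))
    cur <- applyStep(steps[[i]], cur, step_cm1 = step_cm1)
  }
  new("PreprocessChain", steps = steps)
})

#' Apply a fitted chain to spectra
#'
#' @param chain a fitted [PreprocessChain-class]
#' @param x spectra (SpectraSet or matrix) on the training grid
#' @return transformed spectra, same container as the input
#' @export
setMethod("applyChain", "PreprocessChain", function(chain, x, ...) {
  if (!isFitted(chain)) stop("chain has unfitted steps; call fitChain() first")
  cur <- as_spectra_matrix(x)
  step_cm1 <- if (is(x, "SpectraSet")) diff(wavenumbers(x)[1:2]) else 1
  for (i in seq_along(chain@steps))
    cur <- tryCatch(applyStep(chain@steps[[i]], cur, step_cm1 = step_cm1),
      error = function(e) stop(sprintf("chain step %d: %s", i,
                                       conditionMessage(e)), call. = FALSE))
  rewrap(x, cur)
})

#' Fit a chain on calibration spectra and apply it to a target set
#'
#' Convenience wrapper enforcing the fit-on-calibration contract: stateful
#' steps never see the target spectra during fitting.
#'
#' @param chain a [PreprocessChain-class]
#' @param calibration calibration spectra
#' @param target spectra to transform (may be the calibration set itself)
#' @return list with elements `chain` (fitted) and `target` (transformed)
#' @export
chainFitApply <- function(chain, calibration, target) {
  fc <- fitChain(chain, calibration)
  list(chain = fc, target = applyChain(fc, target))
}

#' Parse a named preprocessing chain
#'
#' Accepts the compact labels used in NIR practice, e.g. `"MSC+SG9+FD"`:
#' `MSC`, `SNV`, `SGn` (Savitzky-Golay with an n-point window), `FD`/`SD`
#' (first/second derivative, attached to the preceding SG step or given a
#' default window). The local polynomial order defaults to 2.
#'
#' @param label chain label, `+`-separated
#' @param polyorder polynomial order for all SG steps
#' @param defaultWindow window used when FD/SD appears without an SG token
#' @return an (unfitted) [PreprocessChain-class]
#' @examples
#' parseChain("MSC+SG9+FD")
#' @export
parseChain <- function(label, polyorder = 2L, defaultWindow = 9L) {
  toks <- toupper(trimws(strsplit(label, "+", fixed = TRUE)[[1]]))
  toks <- toks[nzchar(toks)]
  steps <- list()
  for (tk in toks) {
    if (tk == "MSC") steps <- c(steps, mscStep())
    else if (tk == "SNV") steps <- c(steps, snvStep())
    else if (tk == "RAW") next
    else if (grepl("^SG[0-9]+$", tk))
      steps <- c(steps, sgStep(as.integer(sub("SG", "", tk)), polyorder, 0L))
    else if (tk %in% c("FD", "SD")) {
      d <- if (tk == "FD") 1L else 2L
      last <- length(steps)
      if (last > 0 && is(steps[[last]], "SGStep") && steps[[last]]@deriv == 0L)
        steps[[last]] <- sgStep(steps[[last]]@window,
                                max(polyorder, d), d)
      else steps <- c(steps, sgStep(defaultWindow, max(polyorder, d), d))
    } else stop(sprintf("unknown preprocessing token '%s'", tk))
  }
  new("PreprocessChain", steps = steps)
}

# compact label for a chain (inverse of parseChain for standard chains)
chainLabel <- function(chain) {
  if (!length(chain@steps)) return("raw")
  lab <- vapply(chain@steps, function(s) {
    if (is(s, "MSCStep")) "MSC"
    else if (is(s, "SNVStep")) "SNV"
    else if (is(s, "SGStep")) {
      base <- paste0("SG", s@window)
      if (s@deriv == 1L) paste0(base, "+FD")
      else if (s@deriv == 2L) paste0(base, "+SD") else base
    } else class(s)
  }, character(1))
  paste(lab, collapse = "+")
}
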