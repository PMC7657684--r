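#' @include AllClasses.R
#' @useDynLib steamchem, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Low-level NIPALS PLS1 decomposition
#'
#' Iteratively extracts weight, score and loading vectors with deflation.
#' Exposed for inspection and testing; [fitPLS()] is the user-facing wrapper.
#'
#' @param X predictor matrix (samples x variables); centred internally
#' @param y response vector; centred internally
#' @param ncomp number of latent variables to extract
#' @param tol convergence tolerance of the weight fixed point
#' @param maxit maximum NIPALS iterations per component
#' @return list with `coefficients` (variables x ncomp; column k is the
#'   k-component model), `weights`, `loadings`, `scores`, `q`, `x_mean`,
#'   `y_mean`, `n_extracted`
#' @export
nipalsPls <- function(X, y, ncomp, tol = 1e-10, maxit = 500L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(ncomp >= 1)
  if (ncomp > min(nrow(X) - 1L, ncol(X)))
    stop("ncomp exceeds min(n_samples - 1, n_variables)")
  cpp_nipals_pls(X, y, as.integer(ncomp), tol, as.integer(maxit))
}

# assemble a CalibrationModel from a coefficient vector on (a subset of) X
build_model <- function(method, X, y, coefs, ncomp, selected, wavenumbers,
                        property, preprocess, cv = list(), meta = list()) {
  new("CalibrationModel", method = method, property = property,
      nComponents = as.integer(ncomp),
      wavenumbers = as.numeric(wavenumbers),
      selectedVariables = as.integer(selected),
      xMean = colMeans(X[, seq_along(selected), drop = FALSE]),
      yMean = mean(y), coefficients = as.numeric(coefs),
      preprocess = preprocess, cv = cv, meta = meta)
}

#' Fit a PLS1 calibration model
#'
#' NIPALS partial least squares with mean-centring only (no autoscaling;
#' absorbance variables share units). In the full-rank limit the model
#' coincides with ordinary least squares.
#'
#' @param X predictor matrix (samples x variables), typically preprocessed
#'   absorbances
#' @param y response vector (reference values)
#' @param nLV number of latent variables
#' @param tol,maxit NIPALS convergence controls
#' @param property,wavenumbers,selected,preprocess,cv,meta optional metadata
#'   stored in the model (used by the pipeline); `selected` gives the column
#'   indices of `X` in the full training grid
#' @return a [CalibrationModel-class]
#' @export
fitPLS <- function(X, y, nLV, tol = 1e-10, maxit = 500L,
                   property = "", wavenumbers = seq_len(ncol(X)),
                   selected = seq_len(ncol(X)),
                   preprocess = preprocessChain(), cv = list(),
                   meta = list()) {
  X <- as.matrix(X)
  fit <- nipalsPls(X, y, nLV, tol, maxit)
  build_model("PLS", X, y, fit$coefficients[, nLV], nLV, selected,
              wavenumbers, property, preprocess, cv, meta)
}

# dual-space PCA regression pieces shared by fitPCR and its LOO-CV:
# eigen-decompose the n x n Gram matrix of centred X and accumulate
# original-space coefficient vectors for 1..npc components.
pcr_coef_path <- function(Xc, yc, npc) {
  K <- tcrossprod(Xc)
  eg <- eigen(K, symmetric = TRUE)
  keep <- which(eg$values > max(eg$values) * 1e-12)
  npc_eff <- min(npc, length(keep))
  B <- matrix(0, ncol(Xc), npc)
  b <- numeric(ncol(Xc))
  V <- matrix(0, ncol(Xc), npc_eff)
  for (k in seq_len(npc_eff)) {
    u <- eg$vectors[, k]
    d2 <- eg$values[k]
    v <- crossprod(Xc, u) / sqrt(d2)       # unit-norm loading
    V[, k] <- v
    b <- b + v * (sum(u * yc) / sqrt(d2))  # gamma_k / d_k
    B[, k] <- b
  }
  for (k in seq_len(npc)[-seq_len(npc_eff)]) B[, k] <- b
  list(B = B, loadings = V, eigenvalues = eg$values[seq_len(npc_eff)],
       n_effective = npc_eff)
}

#' Fit a principal component regression model
#'
#' PCA of the mean-centred predictors followed by least squares of the
#' response on the leading component scores; coefficients are folded back to
#' the original variable space. With all components the model equals ordinary
#' least squares.
#'
#' @inheritParams fitPLS
#' @param nPC number of principal components
#' @return a [CalibrationModel-class]; the attribute `"loadings"` carries the
#'   unit-norm loading vectors
#' @export
fitPCR <- function(X, y, nPC, property = "",
                   wavenumbers = seq_len(ncol(X)),
                   selected = seq_len(ncol(X)),
                   preprocess = preprocessChain(), cv = list(),
                   meta = list()) {
  X <- as.matrix(X)
  if (nPC > min(nrow(X) - 1L, ncol(X)))
    stop("nPC exceeds min(n_samples - 1, n_variables)")
  Xc <- sweep(X, 2, colMeans(X))
  path <- pcr_coef_path(Xc, y - mean(y), nPC)
  m <- build_model("PCR", X, y, path$B[, nPC], nPC, selected, wavenumbers,
                   property, preprocess, cv, meta)
  attr(m, "loadings") <- path$loadings
  m
}

#' Stepwise multiple linear regression on wavelength variables
#'
#' Forward selection with backward elimination: at each step the variable
#' with the largest partial F enters if it exceeds `fEnter`; any included
#' variable whose partial F falls below `fRemove` is then dropped. Stops when
#' no change occurs or `maxTerms` is reached. Exact duplicates of included
#' variables are never selected (their residual variance is zero), and ties
#' resolve to the lowest column index.
#'
#' @inheritParams fitPLS
#' @param fEnter,fRemove F-to-enter and F-to-remove thresholds
#'   (`fRemove < fEnter`)
#' @param maxTerms maximum number of selected variables
#' @return a [CalibrationModel-class] with `nComponents` = selected-term count
#' @export
fitSMLR <- function(X, y, fEnter = 4.0, fRemove = 3.9, maxTerms = 10L,
                    property = "", wavenumbers = seq_len(ncol(X)),
                    selected = seq_len(ncol(X)),
                    preprocess = preprocessChain(), meta = list()) {
  X <- as.matrix(X)
  if (fRemove >= fEnter) stop("fRemove must be smaller than fEnter")
  if (maxTerms < 1) stop("maxTerms must be >= 1")
  n <- nrow(X)
  included <- integer(0)
  refresh <- function(inc) {
    Q <- qr.Q(qr(cbind(1, X[, inc, drop = FALSE])))
    r <- y - Q %*% crossprod(Q, y)
    list(Q = Q, r = as.numeric(r), SSE = sum(r^2))
  }
  st <- refresh(included)
  for (iter in seq_len(100L)) {
    p <- length(included)
    changed <- FALSE
    # forward step
    if (p < maxTerms && n - p - 2 > 0) {
      Z <- X - st$Q %*% crossprod(st$Q, X)
      zz <- colSums(Z^2)
      ok <- zz > max(zz) * 1e-10
      num <- rep(-Inf, ncol(X))
      num[ok] <- as.numeric(crossprod(Z[, ok, drop = FALSE], st$r))^2 / zz[ok]
      num[included] <- -Inf
      best <- which.max(num)
      # clamp: an exact fit can leave SSE - num at a tiny negative rounding
      denom <- max(st$SSE - num[best], 0) / (n - p - 2)
      Fstat <- if (denom == 0) Inf else num[best] / denom
      if (num[best] > 0 && Fstat > fEnter) {
        included <- c(included, best)
        st <- refresh(included)
        changed <- TRUE
      }
    }
    if (length(included) == 0)
      stop("no informative variable passes the F-to-enter threshold")
    # backward step
    if (length(included) > 1) {
      fit <- stats::lm(y ~ X[, included, drop = FALSE])
      tv <- stats::coef(summary(fit))[-1, "t value"]
      Fpart <- tv^2
      worst <- which.min(Fpart)
      if (is.finite(Fpart[worst]) && Fpart[worst] < fRemove) {
        included <- included[-worst]
        st <- refresh(included)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  included <- sort(included)
  fit <- stats::lm(y ~ X[, included, drop = FALSE])
  b <- as.numeric(stats::coef(fit))[-1]
  Xs <- X[, included, drop = FALSE]
  new("CalibrationModel", method = "SMLR", property = property,
      nComponents = length(included),
      wavenumbers = as.numeric(wavenumbers),
      selectedVariables = as.integer(selected[included]),
      xMean = colMeans(Xs), yMean = mean(y), coefficients = b,
      preprocess = preprocess, cv = list(), meta = meta)
}

#' Leave-one-out RMSECV over component counts
#'
#' For every component count `k = 1..maxK`, each sample is left out in turn,
#' the model is refitted on the remainder and the held-out sample predicted;
#' `RMSECV(k)` is the root mean square of those prediction errors. The chosen
#' component count is the global minimiser, with ties resolved towards the
#' smallest k (parsimony).
#'
#' @param X predictor matrix (samples x variables)
#' @param y response vector
#' @param maxK largest component count to evaluate
#' @param method `"pls"` (NIPALS) or `"pcr"`
#' @param tol,maxit NIPALS controls (PLS only)
#' @return list: `rmsecv_by_k`, `chosen_k`, `predictions` (samples x maxK
#'   matrix of leave-one-out predictions)
#' @export
loocvRMSECV <- function(X, y, maxK, method = c("pls", "pcr"),
                        tol = 1e-10, maxit = 500L) {
  method <- match.arg(method)
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < maxK + 2) stop("need at least maxK + 2 samples for leave-one-out")
  if (var(y) < .Machine$double.eps)
    stop("no variance in response")
  if (method == "pls") {
    pred <- cpp_pls_loocv(X, y, as.integer(maxK), tol, as.integer(maxit))
  } else {
    pred <- matrix(0, n, maxK)
    for (i in seq_len(n)) {
      Xi <- X[-i, , drop = FALSE]
      yi <- y[-i]
      xm <- colMeans(Xi)
      ym <- mean(yi)
      path <- pcr_coef_path(sweep(Xi, 2, xm), yi - ym,
                            min(maxK, n - 2L, ncol(X)))
      xc <- X[i, ] - xm
      for (k in seq_len(maxK))
        pred[i, k] <- ym + sum(xc * path$B[, min(k, ncol(path$B))])
    }
  }
  rmsecv <- sqrt(colMeans((pred - y)^2))
  # smallest k within a hair of the minimum: exact ties (and floating-point
  # ties on effectively rank-deficient data) resolve to the parsimonious k
  lo <- min(rmsecv)
  chosen <- which(rmsecv <= lo + max(1e-12, 1e-9 * lo))[1]
  list(rmsecv_by_k = rmsecv, chosen_k = as.integer(chosen),
       predictions = pred)
}

#' Predict from a fitted calibration model
#'
#' Applies the model's fitted preprocessing chain (trained state only), picks
#' the model's selected variables and evaluates
#' `yhat = yMean + (x - xMean) %*% coefficients`.
#'
#' @param object a [CalibrationModel-class]
#' @param newdata a [SpectraSet-class] on the training grid, or a raw
#'   samples-by-wavenumbers matrix on that grid
#' @param preprocessed set `TRUE` if `newdata` is already preprocessed (the
#'   chain is then skipped)
#' @return numeric vector of predictions, one per spectrum
#' @export
setMethod("predict", "CalibrationModel",
  function(object, newdata, preprocessed = FALSE, ...) {
  m <- as_spectra_matrix(newdata)
  if (!preprocessed) {
    if (ncol(m) != length(object@wavenumbers))
      stop("grid mismatch: spectra are not on the model's training grid")
    if (is(newdata, "SpectraSet") &&
        max(abs(wavenumbers(newdata) - object@wavenumbers)) > 1e-6)
      stop("grid mismatch: spectra are not on the model's training grid")
    s <- SpectraSet(m, object@wavenumbers)
    m <- absorbance(applyChain(object@preprocess, s))
  }
  xs <- m[, object@selectedVariables, drop = FALSE]
  as.numeric(object@yMean +
             sweep(xs, 2, object@xMean) %*% object@coefficients)
})
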