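#' @include AllClasses.R
NULL

#' Principal component scores of a spectra set
#'
#' PCA of the mean-centred (unscaled) absorbance matrix.
#'
#' @param x a [SpectraSet-class] or samples-by-wavenumbers matrix
#' @param nPCs number of leading components to keep
#' @return list: `scores` (samples x nPCs), `explained` (variance fractions,
#'   descending, one per kept PC), `loadings`, `center`
#' @export
pcaScores <- function(x, nPCs = 3L) {
  m <- as_spectra_matrix(x)
  kmax <- min(nrow(m) - 1L, ncol(m))
  if (nPCs > kmax)
    stop(sprintf("nPCs = %d exceeds min(n_samples - 1, n_points) = %d",
                 nPCs, kmax))
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  tot <- sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(nPCs), drop = FALSE],
       explained = pc$sdev[seq_len(nPCs)]^2 / tot,
       loadings = pc$rotation[, seq_len(nPCs), drop = FALSE],
       center = pc$center)
}

#' Flag outliers in score space
#'
#' Hotelling-style screening: the statistic is the squared Mahalanobis
#' distance of each score row from the score mean; a sample is flagged when
#' its distance (in SD units, i.e. the square root of the statistic) exceeds
#' `thresholdSd`. A singular score covariance falls back to its diagonal with
#' a warning; zero-variance directions contribute nothing.
#'
#' @param scores numeric matrix of scores (samples x components)
#' @param thresholdSd distance threshold in standard-deviation units
#' @return an [OutlierReport-class]; `statistic` holds squared distances
#' @export
scoreOutliers <- function(scores, thresholdSd = 3) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 5) stop("need at least 5 samples for outlier screening")
  ctr <- colMeans(scores)
  cv <- stats::cov(scores)
  stat <- tryCatch(stats::mahalanobis(scores, ctr, cv),
    error = function(e) NULL)
  if (is.null(stat) || !all(is.finite(stat))) {
    warning("singular score covariance; falling back to diagonal covariance")
    v <- diag(cv)
    act <- v > .Machine$double.eps * max(v, 1)
    d <- sweep(scores[, act, drop = FALSE], 2, ctr[act])
    stat <- rowSums(sweep(d^2, 2, v[act], `/`))
  }
  flagged <- which(sqrt(stat) > thresholdSd)
  new("OutlierReport", flagged = as.integer(flagged),
      statistic = as.numeric(stat), threshold = thresholdSd,
      kind = "squared Mahalanobis distance (score space)")
}

#' Mahalanobis-distance spectral outlier screening
#'
#' Convenience wrapper used before PCR fitting: computes PCA scores of the
#' (preprocessed) spectra and flags samples by Mahalanobis distance in that
#' score space. Flagging is invariant to sample order.
#'
#' @param x spectra (SpectraSet or matrix), already preprocessed
#' @param nComponents score-space dimension
#' @param thresholdSd distance threshold in SD units
#' @return an [OutlierReport-class]
#' @export
mahalanobisOutliers <- function(x, nComponents = 3L, thresholdSd = 3) {
  sc <- pcaScores(x, nComponents)$scores
  scoreOutliers(sc, thresholdSd)
}

#' Kennard-Stone calibration/validation partition
#'
#' Classic maximin design: seed with the two mutually farthest samples
#' (Euclidean distance, typically on preprocessed spectra), then repeatedly
#' add the candidate whose minimum distance to the already-selected set is
#' largest. Ties are broken towards the lowest sample index, making the split
#' deterministic. The remainder forms the validation set.
#'
#' @param x a [SpectraSet-class] or samples-by-wavenumbers matrix
#' @param nCalibration number of calibration samples (2 <= nCalibration < n)
#' @return a [SplitResult-class]; calibration indices are in selection order
#' @export
kennardStone <- function(x, nCalibration) {
  m <- as_spectra_matrix(x)
  n <- nrow(m)
  if (nCalibration < 2 || nCalibration >= n)
    stop("nCalibration must satisfy 2 <= nCalibration < n_samples")
  D <- as.matrix(stats::dist(m))
  # seed: mutually farthest pair, lowest indices on ties
  mx <- max(D)
  cand <- which(D == mx, arr.ind = TRUE)
  cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  sel <- as.integer(cand[1, ])
  mind <- pmin(D[, sel[1]], D[, sel[2]])
  mind[sel] <- -Inf
  while (length(sel) < nCalibration) {
    nxt <- unname(which.max(mind))      # which.max takes the lowest index on ties
    sel <- c(sel, nxt)
    mind <- pmin(mind, D[, nxt])
    mind[nxt] <- -Inf
  }
  new("SplitResult", calibration = as.integer(unname(sel)),
      validation = as.integer(setdiff(seq_len(n), sel)))
}
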