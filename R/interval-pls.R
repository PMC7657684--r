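#' @include AllClasses.R calibration.R
NULL

#' Partition a spectral range into equal-width intervals
#'
#' Divides `sourceRange` into `k` contiguous equal-width half-open intervals
#' `[low, high)` (the last interval also includes the range's upper bound).
#' Each grid point in the range belongs to exactly one interval.
#'
#' @param wavenumbers full ascending wavenumber grid (cm-1)
#' @param k number of intervals (>= 2)
#' @param sourceRange `(low, high)` in cm-1; must lie within the grid
#' @return list of class `intervalSet`: `k`, `bounds` (k x 2 matrix, cm-1),
#'   `source_range`, and `indices` (list of grid-column index vectors)
#' @examples
#' iv <- makeIntervals(gridSeq(wavenumberGrid()), 20, c(4000, 10000))
#' iv$bounds[1, ]   # 4000 4300
#' @export
makeIntervals <- function(wavenumbers, k, sourceRange = c(4000, 10000)) {
  if (k < 2) stop("k must be >= 2")
  lo <- sourceRange[1]; hi <- sourceRange[2]
  if (lo < min(wavenumbers) - 1e-9 || hi > max(wavenumbers) + 1e-9)
    stop("sourceRange must lie within the grid")
  inRange <- which(wavenumbers >= lo - 1e-9 & wavenumbers <= hi + 1e-9)
  if (k > length(inRange))
    stop("k exceeds the number of grid points in the range")
  w <- (hi - lo) / k
  bounds <- cbind(low = lo + (seq_len(k) - 1) * w, high = lo + seq_len(k) * w)
  assign_iv <- pmin(k, floor((wavenumbers[inRange] - lo) / w) + 1L)
  indices <- split(inRange, factor(assign_iv, levels = seq_len(k)))
  names(indices) <- NULL
  structure(list(k = as.integer(k), bounds = bounds,
                 source_range = c(lo, hi), indices = indices),
            class = "intervalSet")
}

#' Exhaustive synergy-interval PLS search
#'
#' For every configured interval count, the spectrum (restricted to
#' `sourceRange`) is partitioned into equal-width intervals and every
#' combination of `comboSizes` intervals is scored: the combination's
#' variables are concatenated, the latent-variable count is chosen by
#' leave-one-out RMSECV (up to `maxLV`) and the minimum RMSECV recorded. The
#' global best combination wins; the full ranked leaderboard is returned.
#' The search is exhaustive and deterministic.
#'
#' @param X preprocessed calibration matrix (samples x wavenumbers, full grid)
#' @param y calibration response
#' @param wavenumbers full wavenumber grid matching `ncol(X)`
#' @param intervalCounts interval counts to try (e.g. `c(10, 15, 20)`)
#' @param comboSizes combination sizes to try (each >= 2)
#' @param maxLV largest latent-variable count offered to the inner
#'   cross-validation
#' @param sourceRange spectral range searched, cm-1
#' @param property,preprocess metadata forwarded to the winning model
#' @param tol,maxit NIPALS controls
#' @return a [SiplsResult-class]
#' @export
siplsSearch <- function(X, y, wavenumbers,
                        intervalCounts = c(10L, 15L, 20L),
                        comboSizes = 2L, maxLV = 10L,
                        sourceRange = c(4000, 10000),
                        property = "", preprocess = preprocessChain(),
                        tol = 1e-10, maxit = 500L) {
  X <- as.matrix(X)
  if (ncol(X) != length(wavenumbers))
    stop("wavenumbers must match the columns of X")
  if (any(comboSizes < 2)) stop("combination sizes must be >= 2")
  if (!length(intervalCounts) || !length(comboSizes))
    stop("empty search space")
  rows <- list()
  bestRow <- NULL
  for (k in intervalCounts) {
    iv <- makeIntervals(wavenumbers, k, sourceRange)
    for (s in comboSizes) {
      if (s > k) next
      combos <- utils::combn(k, s)
      for (ci in seq_len(ncol(combos))) {
        combo <- combos[, ci]
        cols <- sort(unlist(iv$indices[combo]))
        cv <- loocvRMSECV(X[, cols, drop = FALSE], y,
                          min(maxLV, length(cols), nrow(X) - 2L),
                          method = "pls", tol = tol, maxit = maxit)
        row <- list(k = k, combination = paste(combo, collapse = "+"),
                    size = s, n_lv = cv$chosen_k,
                    rmsecv = cv$rmsecv_by_k[cv$chosen_k])
        rows[[length(rows) + 1L]] <- row
        if (is.null(bestRow) || row$rmsecv < bestRow$rmsecv - 1e-15)
          bestRow <- c(row, list(combo = combo, cols = cols,
                                 bounds = iv$bounds[combo, , drop = FALSE]))
      }
    }
  }
  if (!length(rows)) stop("empty search space")
  lb <- do.call(rbind, lapply(rows, function(r)
    data.frame(k = r$k, combination = r$combination, size = r$size,
               n_lv = r$n_lv, rmsecv = r$rmsecv, stringsAsFactors = FALSE)))
  lb <- lb[order(lb$rmsecv), , drop = FALSE]
  rownames(lb) <- NULL
  cv <- loocvRMSECV(X[, bestRow$cols, drop = FALSE], y,
                    min(maxLV, length(bestRow$cols), nrow(X) - 2L),
                    method = "pls", tol = tol, maxit = maxit)
  model <- fitPLS(X[, bestRow$cols, drop = FALSE], y, cv$chosen_k,
                  tol = tol, maxit = maxit, property = property,
                  wavenumbers = wavenumbers, selected = bestRow$cols,
                  preprocess = preprocess,
                  cv = list(rmsecv_by_k = cv$rmsecv_by_k,
                            chosen_k = cv$chosen_k),
                  meta = list(intervals = bestRow$combination,
                              interval_count = bestRow$k))
  model@method <- "SiPLS"
  new("SiplsResult", bestModel = model,
      bestCombination = as.integer(bestRow$combo),
      bestBounds = bestRow$bounds, bestK = as.integer(bestRow$k),
      rmsecv = bestRow$rmsecv, leaderboard = lb)
}
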