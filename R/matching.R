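# Voxelwise dictionary matching by normalized correlation.
#
# Each measured echo train (row of the signal matrix S) is compared with every
# dictionary column through the matrix product C = S x D after L2
# normalization of the rows of S; the argmax of each row of C identifies the
# best-fitting (wT2, FF, B1) combination. Computed in voxel batches to bound
# memory.

normalize_rows <- function(mat) {
  nrm <- sqrt(rowSums(mat^2))
  nrm[nrm == 0] <- 1
  mat / nrm
}

#' Match signals against a dictionary (unconstrained)
#'
#' @param signals Matrix of measured echo trains, one voxel per row, one
#'   echo per column (magnitudes).
#' @param dict A [build_dictionary()] result with the same echo count.
#' @param batch_size Number of voxel rows per correlation batch. Batching
#'   only bounds memory; results are identical for any batch size.
#'
#' @return A data.frame with one row per signal: `wt2`, `ff`, `b1`,
#'   `correlation` (best normalized inner product) and `entry` (the matched
#'   dictionary column). Ties resolve to the lowest entry index.
#' @export
match_unconstrained <- function(signals, dict, batch_size = 4096L) {
  signals <- as_signal_rows(signals, dict)
  s <- normalize_rows(signals)
  n <- nrow(s)
  entry <- integer(n)
  corr <- numeric(n)
  for (i0 in seq.int(1L, n, by = batch_size)) {
    idx <- i0:min(i0 + batch_size - 1L, n)
    cmat <- s[idx, , drop = FALSE] %*% dict$matrix
    best <- max.col(cmat, ties.method = "first")
    entry[idx] <- best
    corr[idx] <- cmat[cbind(seq_along(idx), best)]
  }
  data.frame(wt2 = dict$index$wt2[entry], ff = dict$index$ff[entry],
             b1 = dict$index$b1[entry], correlation = corr, entry = entry)
}

#' Match signals with a voxelwise fat-fraction constraint
#'
#' Each voxel's fat fraction is quantized to the nearest grid value and the
#' correlation argmax is restricted to that FF's contiguous entry range, so
#' only wT2 and B1 are fitted. The returned `ff` always equals the quantized
#' constraint.
#'
#' @param signals Matrix of echo trains (voxels x echoes).
#' @param dict A [build_dictionary()] result.
#' @param ff_voxel Fat-fraction constraint per voxel (values outside `[0,1]`
#'   are clamped; `NA` is an error -- see [wt2_fit()] for the unconstrained
#'   fallback).
#' @param batch_size Voxel rows per correlation batch.
#'
#' @return A data.frame as in [match_unconstrained()].
#' @export
match_constrained <- function(signals, dict, ff_voxel, batch_size = 4096L) {
  signals <- as_signal_rows(signals, dict)
  n <- nrow(signals)
  if (length(ff_voxel) != n)
    stop("ff_voxel must supply one value per signal row")
  if (anyNA(ff_voxel))
    stop("ff_voxel contains missing values; handle unconstrained fallback upstream")
  ff_voxel <- pmin(1, pmax(0, ff_voxel))
  ffq_idx <- nearest_index(ff_voxel, dict$grid$ff)
  s <- normalize_rows(signals)
  block <- length(dict$grid$b1) * length(dict$grid$wt2)
  entry <- integer(n)
  corr <- numeric(n)
  for (fi in sort(unique(ffq_idx))) {
    rows <- which(ffq_idx == fi)
    cols <- dict$ff_group_offsets[fi] + 0:(block - 1L)
    dsub <- dict$matrix[, cols, drop = FALSE]
    for (i0 in seq.int(1L, length(rows), by = batch_size)) {
      idx <- rows[i0:min(i0 + batch_size - 1L, length(rows))]
      cmat <- s[idx, , drop = FALSE] %*% dsub
      best <- max.col(cmat, ties.method = "first")
      entry[idx] <- cols[best]
      corr[idx] <- cmat[cbind(seq_along(idx), best)]
    }
  }
  data.frame(wt2 = dict$index$wt2[entry], ff = dict$index$ff[entry],
             b1 = dict$index$b1[entry], correlation = corr, entry = entry)
}

# index of the nearest value of a sorted grid, ties to the lower value
nearest_index <- function(x, grid) {
  if (length(grid) == 1L) return(rep(1L, length(x)))
  i <- findInterval(x, grid, all.inside = TRUE)
  lo <- grid[i]; hi <- grid[i + 1L]
  ifelse(x - lo <= hi - x, i, i + 1L)
}

as_signal_rows <- function(signals, dict) {
  if (is.null(dim(signals))) signals <- matrix(signals, nrow = 1)
  if (ncol(signals) != nrow(dict$matrix))
    stop(sprintf("signal echo count (%d) does not match dictionary (%d)",
                 ncol(signals), nrow(dict$matrix)))
  signals
}

#' Foreground mask from the first-echo image
#'
#' Thresholds the first-echo magnitude image at a fraction of its robust
#' maximum (the 99th percentile), excluding background voxels from the fit.
#'
#' @param first_echo 3D array of first-echo intensities.
#' @param threshold_fraction Fraction of the robust maximum in `[0, 1)`;
#'   0 keeps every voxel with a positive intensity.
#'
#' @return Logical array of the same shape. Warns if the mask is empty.
#' @export
make_mask <- function(first_echo, threshold_fraction = 0.05) {
  if (threshold_fraction < 0 || threshold_fraction >= 1)
    stop("threshold_fraction must lie in [0, 1)")
  robust_max <- stats::quantile(first_echo, 0.99, na.rm = TRUE, names = FALSE)
  mask <- first_echo > threshold_fraction * robust_max & first_echo > 0
  mask[is.na(mask)] <- FALSE
  if (!any(mask)) warning("mask is empty: no voxel exceeds the threshold")
  mask
}
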