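# Signal dictionary over the (wT2, fat fraction, B1) parameter grid.

#' Parameter grid for dictionary matching
#'
#' Defaults: 60 linearly spaced water-T2 values in 20-80 ms, 101 fat-fraction
#' values in 0-1 and 20 B1 factors in 0.4-1.4, i.e. 121200 combinations.
#'
#' @param wt2 Water T2 values in ms (strictly increasing, or one value).
#' @param ff Fat-fraction values in `[0, 1]`.
#' @param b1 B1 factors (> 0).
#'
#' @return An object of class `wt2_grid`.
#' @examples
#' g <- wt2_grid()
#' length(g$wt2) * length(g$ff) * length(g$b1)  # 121200
#' @export
wt2_grid <- function(wt2 = seq(20, 80, length.out = 60),
                     ff = seq(0, 1, length.out = 101),
                     b1 = seq(0.4, 1.4, length.out = 20)) {
  check_axis <- function(x, name) {
    if (length(x) == 0 || anyNA(x)) stop(name, " axis must be non-empty and finite")
    if (length(x) > 1 && any(diff(x) <= 0))
      stop(name, " axis must be strictly increasing")
    as.numeric(x)
  }
  wt2 <- check_axis(wt2, "wt2")
  ff <- check_axis(ff, "ff")
  b1 <- check_axis(b1, "b1")
  if (any(wt2 <= 0)) stop("wt2 values must be positive")
  if (any(ff < 0 | ff > 1)) stop("ff values must lie in [0, 1]")
  if (any(b1 <= 0)) stop("b1 values must be positive")
  structure(list(wt2 = wt2, ff = ff, b1 = b1), class = "wt2_grid")
}

#' @export
print.wt2_grid <- function(x, ...) {
  cat(sprintf("Parameter grid: %d wT2 [%g, %g] ms x %d FF [%g, %g] x %d B1 [%g, %g] = %d entries\n",
              length(x$wt2), min(x$wt2), max(x$wt2),
              length(x$ff), min(x$ff), max(x$ff),
              length(x$b1), min(x$b1), max(x$b1),
              length(x$wt2) * length(x$ff) * length(x$b1)))
  invisible(x)
}

#' Build the signal dictionary
#'
#' Simulates the two-compartment EPG signal for every grid combination and
#' stores the echo trains as L2-normalized columns. Entries are ordered
#' FF-major (FF slowest, then B1, then wT2 fastest), so all entries sharing a
#' fat-fraction value occupy one contiguous column range; this makes the
#' fat-fraction-constrained match a contiguous-range argmax. The build is
#' deterministic and cheap enough to be redone at every run, so no caching
#' layer exists.
#'
#' @param grid A [wt2_grid()].
#' @param seq A [sequence_params()].
#' @param profile A slice-profile table.
#' @param fat_t2 Fat T2 in ms (default 151; see [estimate_fat_t2()]).
#' @param t1_water,t1_fat Fixed compartment T1 values in ms.
#'
#' @return An object of class `signal_dictionary`: `matrix` (echoes x
#'   entries, unit-norm columns), `index` (data.frame with `wt2`, `ff`, `b1`
#'   per entry), `grid`, `seq`, `fat_t2`, and `ff_group_offsets` (first
#'   column of each FF block).
#' @export
build_dictionary <- function(grid, seq, profile, fat_t2 = 151,
                             t1_water = 1400, t1_fat = 365) {
  stopifnot(inherits(grid, "wt2_grid"), inherits(seq, "sequence_params"))
  if (!is.finite(fat_t2) || fat_t2 <= 0) stop("fat_t2 must be positive (ms)")
  n_wt2 <- length(grid$wt2); n_ff <- length(grid$ff); n_b1 <- length(grid$b1)
  # FF-major ordering: ff slowest, then b1, then wt2 fastest
  index <- data.frame(
    wt2 = rep(grid$wt2, times = n_ff * n_b1),
    ff = rep(grid$ff, each = n_b1 * n_wt2),
    b1 = rep(rep(grid$b1, each = n_wt2), times = n_ff)
  )
  mat <- epg_voxel_trains(index$wt2, index$ff, index$b1, seq, profile,
                          fat_t2 = fat_t2, t1_water = t1_water,
                          t1_fat = t1_fat)
  mat <- normalize_columns(mat)
  block <- n_b1 * n_wt2
  structure(list(
    matrix = mat,
    index = index,
    grid = grid,
    seq = seq,
    fat_t2 = fat_t2,
    t1_water = t1_water,
    t1_fat = t1_fat,
    ff_group_offsets = seq.int(1L, n_ff * block, by = block)
  ), class = "signal_dictionary")
}

normalize_columns <- function(mat) {
  nrm <- sqrt(colSums(mat^2))
  nrm[nrm == 0] <- 1
  # columns already at unit norm are left untouched so renormalization is
  # exactly idempotent
  nrm[abs(nrm - 1) < 1e-12] <- 1
  sweep(mat, 2, nrm, "/")
}

#' @export
print.signal_dictionary <- function(x, ...) {
  cat(sprintf("Signal dictionary: %d echoes x %d entries (fat T2 = %g ms)\n",
              nrow(x$matrix), ncol(x$matrix), x$fat_t2))
  print(x$grid)
  invisible(x)
}

#' Truncate an echo train container to the first echoes
#'
#' Discarding late echoes emulates a shorter acquisition. Dictionary columns
#' are re-normalized to unit L2 norm after truncation.
#'
#' @param x A `signal_dictionary` or a `mese_series`.
#' @param n_keep Number of leading echoes to keep (between 2 and the number
#'   of echoes present).
#' @return Object of the same class with `n_keep` echoes.
#' @export
truncate_echoes <- function(x, n_keep) UseMethod("truncate_echoes")

#' @export
truncate_echoes.signal_dictionary <- function(x, n_keep) {
  n_keep <- as.integer(n_keep)
  if (n_keep < 2L || n_keep > nrow(x$matrix))
    stop("n_keep must be between 2 and the number of echoes (", nrow(x$matrix), ")")
  x$matrix <- normalize_columns(x$matrix[seq_len(n_keep), , drop = FALSE])
  x$seq$n_echoes <- n_keep
  x
}

#' @export
truncate_echoes.mese_series <- function(x, n_keep) {
  n_keep <- as.integer(n_keep)
  n <- length(x$echo_times)
  if (n_keep < 2L || n_keep > n)
    stop("n_keep must be between 2 and the number of echoes (", n, ")")
  x$volume <- x$volume[, , , seq_len(n_keep), drop = FALSE]
  x$echo_times <- x$echo_times[seq_len(n_keep)]
  x
}

#' Estimate fat T2 from subcutaneous-fat echo trains
#'
#' Matches each supplied fat signal against single-compartment EPG
#' dictionaries (T1 = `t1_fat`) spanning a T2 and B1 search grid, using the
#' same normalized-correlation metric as the main matching step, and returns
#' the median of the per-signal best T2 values (mean of the middle pair for
#' an even count).
#'
#' @param fat_signals Matrix of echo trains, one signal per row (or a single
#'   vector).
#' @param seq A [sequence_params()] matching the acquisition.
#' @param profile Slice-profile table.
#' @param t2_search T2 search values in ms (default 80-300 ms in 4 ms steps).
#' @param b1_search B1 search values.
#' @param t1_fat Fat T1 in ms.
#'
#' @return Estimated fat T2 in ms (a value of `t2_search`, or the midpoint
#'   of two for an even signal count).
#' @export
estimate_fat_t2 <- function(fat_signals, seq, profile,
                            t2_search = seq(80, 300, by = 4),
                            b1_search = seq(0.4, 1.4, length.out = 20),
                            t1_fat = 365) {
  if (is.null(dim(fat_signals))) fat_signals <- matrix(fat_signals, nrow = 1)
  if (nrow(fat_signals) < 1) stop("at least one fat signal is required")
  if (ncol(fat_signals) != seq$n_echoes)
    stop("fat signals must have one column per echo")
  combos <- expand.grid(t2 = t2_search, b1 = b1_search)
  mat <- epg_voxel_trains(combos$t2, rep(0, nrow(combos)), combos$b1, seq,
                          profile, t1_water = t1_fat, t1_fat = t1_fat)
  mat <- normalize_columns(mat)
  s <- normalize_rows(fat_signals)
  best <- max.col(s %*% mat, ties.method = "first")
  stats::median(combos$t2[best])
}
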