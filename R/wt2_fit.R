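#' Fit water-T2 maps from a multi-echo spin-echo series
#'
#' The main estimator of the package. For `method = "epg"` a dictionary of
#' slice-profile-integrated EPG echo trains over the (wT2, fat fraction, B1)
#' grid is built and matched voxelwise by normalized correlation,
#' unconstrained or restricted to an externally supplied fat fraction. For
#' `method = "biexp"` / `"monoexp"` each voxel is fitted by bounded nonlinear
#' least squares of the corresponding exponential model (no B1 or
#' slice-profile correction in that path).
#'
#' @param mese A `mese_series` (see [read_mese()] or [make_phantom()]).
#' @param method `"epg"` (dictionary matching, default), `"biexp"` or
#'   `"monoexp"`.
#' @param ff Optional fat-fraction constraint: an `ff_volume` (resampled onto
#'   the MESE grid by header geometry) or a 3D array already on the MESE
#'   grid. Voxels with a missing constraint (e.g. outside the constraint
#'   volume's field of view) fall back to unconstrained matching.
#' @param echoes Number of leading echoes to use (default: all).
#' @param mask Logical array of voxels to fit, or `NULL` to threshold the
#'   first-echo image (see [make_mask()]).
#' @param grid [wt2_grid()] for the dictionary (EPG only).
#' @param profile Slice-profile table; default [build_profile_table()] with
#'   the sequence's refocusing width factor.
#' @param seq A [sequence_params()]; by default derived from the series' echo
#'   times (17-echo protocol defaults otherwise).
#' @param fat_t2 Fat T2 in ms (default 151), or `"auto"` together with
#'   `fat_roi` to estimate it from subcutaneous-fat voxels via
#'   [estimate_fat_t2()].
#' @param fat_roi Logical array marking subcutaneous fat (required for
#'   `fat_t2 = "auto"`).
#' @param mask_threshold Threshold fraction for the automatic mask.
#' @param batch_size Voxel rows per matching batch.
#' @param interpolation Interpolation for the fat-fraction resampling.
#' @param verbose Print stage timings.
#'
#' @return An object of class `wt2_fit` with components `maps` (a
#'   `parameter_maps`: `wt2` ms, `ff`, `b1`, `correlation`, NaN outside the
#'   mask), `method`, `config`, `n_fitted`, `n_unconstrained_fallback`,
#'   `timing` and `call`. Methods: [print.wt2_fit()], [summary.wt2_fit()],
#'   [coef.wt2_fit()], [plot.wt2_fit()].
#' @examples
#' ph <- make_phantom(phantom_spec(shape = c(24, 24, 1), noise_sigma = 0),
#'                    sequence_params(n_echoes = 7), hard_pulse_profile())
#' fit <- wt2_fit(ph$mese, grid = wt2_grid(b1 = 1), profile = hard_pulse_profile(),
#'                seq = sequence_params(n_echoes = 7))
#' summary(fit)
#' @export
wt2_fit <- function(mese,
                    method = c("epg", "biexp", "monoexp"),
                    ff = NULL,
                    echoes = NULL,
                    mask = NULL,
                    grid = wt2_grid(),
                    profile = NULL,
                    seq = NULL,
                    fat_t2 = 151,
                    fat_roi = NULL,
                    mask_threshold = 0.05,
                    batch_size = 4096L,
                    interpolation = c("linear", "nearest"),
                    verbose = FALSE) {
  method <- match.arg(method)
  interpolation <- match.arg(interpolation)
  stopifnot(inherits(mese, "mese_series"))
  t_start <- proc.time()[["elapsed"]]
  timing <- c()
  tic <- function() proc.time()[["elapsed"]]
  lap <- function(name, t0) {
    timing[[name]] <<- tic() - t0
    if (verbose) message(sprintf("  %s: %.2f s", name, timing[[name]]))
  }

  n_avail <- length(mese$echo_times)
  if (!is.null(echoes)) {
    echoes <- as.integer(echoes)
    if (echoes > n_avail)
      stop(sprintf("requested %d echoes but the series has only %d",
                   echoes, n_avail))
    if (echoes < n_avail) mese <- truncate_echoes(mese, echoes)
  }
  te <- mese$echo_times
  esp <- mean(diff(te))
  if (is.null(seq)) {
    seq <- sequence_params(n_echoes = length(te), echo_spacing = esp)
  } else if (seq$n_echoes != length(te)) {
    seq$n_echoes <- length(te)
  }

  d <- dim(mese$volume)[1:3]
  if (is.null(mask))
    mask <- make_mask(array(mese$volume[, , , 1], dim = d), mask_threshold)
  if (!all(dim(mask) == d)) stop("mask must match the MESE spatial dimensions")

  t0 <- tic()
  ff_aligned <- NULL
  if (!is.null(ff)) {
    ff_aligned <- align_ff_to_mese(ff, mese, interpolation)
    lap("align_ff", t0)
  }

  vox <- which(mask)
  if (length(vox) == 0) stop("mask contains no voxels")
  nvol <- prod(d)
  sig <- matrix(aperm(mese$volume, c(4, 1, 2, 3)),
                nrow = length(te))[, vox, drop = FALSE]
  sig <- t(sig)                                 # voxels x echoes

  wt2_map <- array(NaN, dim = d)
  ff_map <- array(NaN, dim = d)
  b1_map <- array(NaN, dim = d)
  corr_map <- array(NaN, dim = d)
  n_fallback <- 0L

  if (method == "epg") {
    if (is.null(profile))
      profile <- build_profile_table(
        exc = pulse_spec(seq$excitation_flip),
        ref = pulse_spec(seq$refocusing_flip),
        width_factor = seq$refocusing_width_factor)
    if (identical(fat_t2, "auto")) {
      if (is.null(fat_roi)) stop("fat_t2 = \"auto\" requires a fat_roi mask")
      fat_sig <- t(matrix(aperm(mese$volume, c(4, 1, 2, 3)),
                          nrow = length(te))[, which(fat_roi), drop = FALSE])
      fat_t2 <- estimate_fat_t2(fat_sig, seq, profile)
      if (verbose) message(sprintf("  estimated fat T2: %.1f ms", fat_t2))
    }
    t0 <- tic()
    dict <- build_dictionary(grid, seq, profile, fat_t2 = fat_t2)
    lap("build_dictionary", t0)

    t0 <- tic()
    if (is.null(ff_aligned)) {
      res <- match_unconstrained(sig, dict, batch_size)
    } else {
      ffv <- ff_aligned[vox]
      has_ff <- !is.na(ffv)
      n_fallback <- sum(!has_ff)
      res <- data.frame(wt2 = rep(NA_real_, length(vox)), ff = NA_real_,
                        b1 = NA_real_, correlation = NA_real_, entry = NA_integer_)
      if (any(has_ff))
        res[has_ff, ] <- match_constrained(sig[has_ff, , drop = FALSE], dict,
                                           ffv[has_ff], batch_size)
      if (n_fallback > 0) {
        warning(sprintf(
          "%d in-mask voxels lack a fat-fraction constraint; fitted unconstrained",
          n_fallback))
        res[!has_ff, ] <- match_unconstrained(sig[!has_ff, , drop = FALSE],
                                              dict, batch_size)
      }
    }
    lap("match", t0)
    wt2_map[vox] <- res$wt2
    ff_map[vox] <- res$ff
    b1_map[vox] <- res$b1
    corr_map[vox] <- res$correlation
  } else {
    if (identical(fat_t2, "auto"))
      stop("fat_t2 = \"auto\" is only available for method = \"epg\"")
    t0 <- tic()
    ffv <- if (!is.null(ff_aligned)) ff_aligned[vox] else rep(NA_real_, length(vox))
    n_nc <- 0L
    for (i in seq_along(vox)) {
      s <- sig[i, ]
      if (method == "monoexp") {
        f <- fit_monoexponential(s, te)
        wt2_map[vox[i]] <- f$t2
        ff_map[vox[i]] <- 0
      } else {
        f <- fit_biexponential(s, te, fat_t2 = fat_t2,
                               ff_fixed = if (is.na(ffv[i])) NULL else ffv[i])
        wt2_map[vox[i]] <- f$wt2
        ff_map[vox[i]] <- f$ff
      }
      if (!f$converged) n_nc <- n_nc + 1L
    }
    if (n_nc > 0) warning(n_nc, " voxel fits did not converge (NaN in maps)")
    lap("expfit", t0)
  }

  timing[["total"]] <- tic() - t_start
  maps <- new_parameter_maps(wt2_map, ff_map, b1_map, corr_map, mese$affine)
  structure(list(
    maps = maps,
    method = method,
    config = list(method = method, echoes = length(te), echo_spacing = esp,
                  tr = seq$tr, fat_t2 = if (is.numeric(fat_t2)) fat_t2 else NA,
                  grid = if (method == "epg")
                    lapply(unclass(grid), range) else NULL,
                  constrained = !is.null(ff),
                  apply_tr_saturation = seq$apply_tr_saturation,
                  mask_threshold = mask_threshold),
    n_fitted = length(vox),
    n_unconstrained_fallback = n_fallback,
    timing = timing,
    call = match.call()
  ), class = "wt2_fit")
}

#' @export
print.wt2_fit <- function(x, ...) {
  cat("Water-T2 fit (", x$method,
      if (x$config$constrained) ", FF-constrained" else ", unconstrained",
      ")\n", sep = "")
  cat(sprintf("  %d voxels fitted with %d echoes in %.1f s\n",
              x$n_fitted, x$config$echoes, x$timing[["total"]]))
  print(x$maps)
  invisible(x)
}

#' Summary of a water-T2 fit
#'
#' @param object A `wt2_fit`.
#' @param ... Unused.
#' @return A `summary.wt2_fit`: per-map quartiles over fitted voxels plus the
#'   fit configuration.
#' @export
summary.wt2_fit <- function(object, ...) {
  qs <- function(v) stats::quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE)
  stats <- rbind(wt2_ms = qs(object$maps$wt2),
                 fat_fraction = qs(object$maps$ff),
                 b1_factor = qs(object$maps$b1),
                 correlation = qs(object$maps$correlation))
  structure(list(stats = stats, config = object$config,
                 n_fitted = object$n_fitted,
                 n_unconstrained_fallback = object$n_unconstrained_fallback),
            class = "summary.wt2_fit")
}

#' @export
print.summary.wt2_fit <- function(x, ...) {
  cat(sprintf("Water-T2 fit: method %s, %d echoes, %d voxels\n",
              x$config$method, x$config$echoes, x$n_fitted))
  if (x$n_unconstrained_fallback > 0)
    cat(sprintf("  %d voxels lacked a fat-fraction constraint\n",
                x$n_unconstrained_fallback))
  print(round(x$stats, 4))
  invisible(x)
}

#' Extract the fitted parameter maps
#'
#' @param object A `wt2_fit`.
#' @param ... Unused.
#' @return Named list of 3D arrays (`wt2`, `ff`, `b1`, `correlation`).
#' @export
coef.wt2_fit <- function(object, ...) {
  object$maps[c("wt2", "ff", "b1", "correlation")]
}

#' Plot fitted parameter maps
#'
#' Displays one slice of the wT2, fat-fraction and B1 maps side by side.
#'
#' @param x A `wt2_fit`.
#' @param slice Slice index (default: middle slice).
#' @param ... Passed to [graphics::image()].
#' @export
plot.wt2_fit <- function(x, slice = NULL, ...) {
  d <- dim(x$maps$wt2)
  if (is.null(slice)) slice <- ceiling(d[3] / 2)
  op <- graphics::par(mfrow = c(1, 3), mar = c(2, 2, 3, 1))
  on.exit(graphics::par(op))
  panels <- list(`wT2 [ms]` = x$maps$wt2, `fat fraction` = x$maps$ff,
                 `B1 factor` = x$maps$b1)
  for (nm in names(panels)) {
    m <- panels[[nm]][, , slice]
    graphics::image(m, main = nm, axes = FALSE, useRaster = TRUE,
                    col = grDevices::hcl.colors(64, "viridis"), ...)
  }
  invisible(x)
}
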