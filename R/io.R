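# NIfTI input/output and header-based alignment of the fat-fraction volume.
#
# Geometry convention: the affine maps 0-based voxel indices (i, j, k) to
# world coordinates in mm (RAS, the NIfTI standard); voxel centers are the
# sampling points. No image registration is performed anywhere: the
# fat-fraction constraint is resampled onto the MESE grid purely from the
# orientation and position information in the image headers.

#' Read a multi-echo spin-echo series
#'
#' Reads a 4D NIfTI volume (x, y, slice, echo) together with its echo times.
#' Echo times come from the `echo_times` argument or from a JSON sidecar next
#' to the image (same basename, `.json` extension) with a field `echo_times`
#' (ms). Echoes are sorted by echo time if needed.
#'
#' @param path Path to a 4D NIfTI file.
#' @param echo_times Optional numeric vector of echo times in ms, one per
#'   volume in the 4th dimension; overrides the sidecar.
#'
#' @return An object of class `mese_series`: `volume` (4D array),
#'   `echo_times` (ms, ascending), `affine` (4x4 voxel-to-world matrix),
#'   `source`.
#' @export
read_mese <- function(path, echo_times = NULL) {
  img <- RNifti::readNifti(path)
  vol <- as.array(img)
  if (is.null(echo_times)) {
    sidecar <- sidecar_path(path)
    if (!file.exists(sidecar))
      stop(path, ": echo times missing; supply `echo_times` or a JSON sidecar ",
           sidecar, " with field `echo_times` (ms)")
    meta <- jsonlite::fromJSON(sidecar)
    if (is.null(meta$echo_times))
      stop(sidecar, ": sidecar lacks an `echo_times` field")
    echo_times <- as.numeric(meta$echo_times)
  }
  # single-slice series may come back 3D (x, y, echo): restore the slice dim
  if (length(dim(vol)) == 3L) {
    if (dim(vol)[3] == length(echo_times)) {
      dim(vol) <- c(dim(vol)[1:2], 1L, dim(vol)[3])
    } else {
      dim(vol) <- c(dim(vol), 1L)
    }
  }
  if (length(dim(vol)) != 4L)
    stop(path, ": expected a 4D multi-echo volume, got ",
         length(dim(vol)), " dimensions")
  if (length(echo_times) != dim(vol)[4])
    stop(sprintf("%s: %d echo times for %d echo volumes", path,
                 length(echo_times), dim(vol)[4]))
  ord <- order(echo_times)
  echo_times <- echo_times[ord]
  vol <- vol[, , , ord, drop = FALSE]
  if (any(diff(echo_times) <= 0))
    stop(path, ": echo times must be strictly increasing after sorting")
  sp <- diff(echo_times)
  if (length(sp) > 1 && (max(sp) - min(sp)) / mean(sp) > 0.01)
    warning(path, ": echo spacing varies by more than 1%")
  new_mese_series(vol, echo_times, nifti_affine(img), source = path)
}

new_mese_series <- function(volume, echo_times, affine, source = "memory") {
  structure(list(volume = volume, echo_times = echo_times, affine = affine,
                 source = source), class = "mese_series")
}

#' @export
print.mese_series <- function(x, ...) {
  d <- dim(x$volume)
  cat(sprintf("MESE series: %d x %d x %d voxels, %d echoes (TE1 %.1f ms, spacing %.1f ms)\n",
              d[1], d[2], d[3], d[4], x$echo_times[1],
              mean(diff(x$echo_times))))
  cat("  source:", x$source, "\n")
  invisible(x)
}

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

nifti_affine <- function(img) {
  aff <- RNifti::xform(img, useQuaternionFirst = FALSE)
  aff <- unclass(aff)
  attributes(aff) <- list(dim = c(4L, 4L))
  aff
}

#' Read a fat-fraction volume
#'
#' Reads a 3D NIfTI fat-fraction map. Volumes whose maximum exceeds 1.5 are
#' taken to be in percent and divided by 100 (`percent_input = TRUE`);
#' values are then clamped to `[0, 1]`.
#'
#' @param path Path to a 3D NIfTI file.
#' @return An object of class `ff_volume`: `values` (3D array in `[0, 1]`),
#'   `affine`, `percent_input`.
#' @export
read_ff <- function(path) {
  img <- RNifti::readNifti(path)
  vals <- as.array(img)
  if (length(dim(vals)) == 4L && dim(vals)[4] == 1L) dim(vals) <- dim(vals)[1:3]
  if (length(dim(vals)) == 2L) dim(vals) <- c(dim(vals), 1L)  # single slice
  if (length(dim(vals)) != 3L)
    stop(path, ": expected a 3D fat-fraction volume")
  new_ff_volume(vals, nifti_affine(img))
}

new_ff_volume <- function(values, affine) {
  percent <- isTRUE(max(values, na.rm = TRUE) > 1.5)
  if (percent) values <- values / 100
  d <- dim(values)
  values <- array(pmin(1, pmax(0, values)), dim = d)  # pmin/pmax drop dims
  structure(list(values = values, affine = affine, percent_input = percent),
            class = "ff_volume")
}

#' Resample a fat-fraction volume onto the MESE grid
#'
#' Maps each MESE voxel center through the MESE affine to world coordinates
#' and through the inverse fat-fraction affine to fractional voxel indices,
#' then samples with trilinear (`"linear"`) or nearest-neighbour
#' interpolation. Voxels falling outside the fat-fraction volume become
#' `NaN`; a warning reports their count (downstream they are fitted
#' unconstrained).
#'
#' @param ff An `ff_volume` (or a plain 3D array already on the MESE grid).
#' @param mese A `mese_series`.
#' @param interpolation `"linear"` (default; the fat fraction is a smooth
#'   quantity) or `"nearest"` for label-like inputs.
#'
#' @return 3D array of fat fractions on the MESE spatial grid.
#' @export
align_ff_to_mese <- function(ff, mese, interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  stopifnot(inherits(mese, "mese_series"))
  if (is.array(ff) && !inherits(ff, "ff_volume")) {
    if (!all(dim(ff) == dim(mese$volume)[1:3]))
      stop("plain-array ff must already match the MESE spatial dimensions")
    return(ff)
  }
  stopifnot(inherits(ff, "ff_volume"))
  a_ff <- ff$affine
  if (abs(det(a_ff[1:3, 1:3])) < 1e-12) stop("fat-fraction affine is singular")
  if (abs(det(mese$affine[1:3, 1:3])) < 1e-12) stop("MESE affine is singular")
  d <- dim(mese$volume)[1:3]
  # 0-based voxel-center index grid of the MESE volume
  ijk <- cbind(
    rep(seq_len(d[1]) - 1, times = d[2] * d[3]),
    rep(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3]),
    rep(seq_len(d[3]) - 1, each = d[1] * d[2])
  )
  m <- solve(a_ff) %*% mese$affine   # MESE voxel -> FF voxel (both 0-based)
  v <- ijk %*% t(m[1:3, 1:3])
  v <- sweep(v, 2, m[1:3, 4], "+")
  out <- sample_volume(ff$values, v, interpolation)
  n_out <- sum(is.na(out))
  if (n_out > 0)
    warning(sprintf("%d of %d MESE voxels fall outside the fat-fraction volume",
                    n_out, nrow(v)))
  array(out, dim = d)
}

# Sample a 3D volume at fractional 0-based coordinates (rows of `v`).
# Out-of-volume coordinates yield NA.
sample_volume <- function(vol, v, interpolation) {
  d <- dim(vol)
  if (interpolation == "nearest") {
    idx <- round(v)
    ok <- idx[, 1] >= 0 & idx[, 1] <= d[1] - 1 &
      idx[, 2] >= 0 & idx[, 2] <= d[2] - 1 &
      idx[, 3] >= 0 & idx[, 3] <= d[3] - 1
    out <- rep(NA_real_, nrow(v))
    out[ok] <- vol[1 + idx[ok, 1] + d[1] * (idx[ok, 2] + d[2] * idx[ok, 3])]
    return(out)
  }
  f <- floor(v)
  w <- v - f
  ok <- f[, 1] >= 0 & f[, 1] <= d[1] - 1 &
    f[, 2] >= 0 & f[, 2] <= d[2] - 1 &
    f[, 3] >= 0 & f[, 3] <= d[3] - 1 &
    v[, 1] <= d[1] - 1 & v[, 2] <= d[2] - 1 & v[, 3] <= d[3] - 1
  out <- rep(NA_real_, nrow(v))
  if (!any(ok)) return(out)
  f <- f[ok, , drop = FALSE]
  w <- w[ok, , drop = FALSE]
  # clamp the upper corner so exact boundary coordinates stay in range
  up <- function(fi, di) pmin(fi + 1, di - 1)
  lin <- function(i, j, k) vol[1 + i + d[1] * (j + d[2] * k)]
  i0 <- f[, 1]; j0 <- f[, 2]; k0 <- f[, 3]
  i1 <- up(i0, d[1]); j1 <- up(j0, d[2]); k1 <- up(k0, d[3])
  wx <- w[, 1]; wy <- w[, 2]; wz <- w[, 3]
  out[ok] <-
    lin(i0, j0, k0) * (1 - wx) * (1 - wy) * (1 - wz) +
    lin(i1, j0, k0) * wx * (1 - wy) * (1 - wz) +
    lin(i0, j1, k0) * (1 - wx) * wy * (1 - wz) +
    lin(i1, j1, k0) * wx * wy * (1 - wz) +
    lin(i0, j0, k1) * (1 - wx) * (1 - wy) * wz +
    lin(i1, j0, k1) * wx * (1 - wy) * wz +
    lin(i0, j1, k1) * (1 - wx) * wy * wz +
    lin(i1, j1, k1) * wx * wy * wz
  out
}

new_parameter_maps <- function(wt2, ff, b1, correlation, affine) {
  structure(list(wt2 = wt2, ff = ff, b1 = b1, correlation = correlation,
                 affine = affine), class = "parameter_maps")
}

#' @export
print.parameter_maps <- function(x, ...) {
  d <- dim(x$wt2)
  n <- sum(!is.na(x$wt2))
  cat(sprintf("Parameter maps: %d x %d x %d voxels, %d fitted\n",
              d[1], d[2], d[3], n))
  if (n > 0)
    cat(sprintf("  wT2 median %.1f ms, FF median %.3f\n",
                stats::median(x$wt2, na.rm = TRUE),
                stats::median(x$ff, na.rm = TRUE)))
  invisible(x)
}

# write a 3D array as float32 NIfTI with the given 0-based voxel->world affine
write_nifti_map <- function(arr, affine, path) {
  pix <- sqrt(colSums(affine[1:3, 1:3]^2))
  img <- RNifti::asNifti(arr, pixdim = pix)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Write parameter maps and a provenance sidecar
#'
#' Writes one 32-bit float NIfTI per map (`wt2_ms`, `ff_fraction`,
#' `b1_fraction`, `correlation`), each carrying the MESE affine, plus a
#' `run_info.json` sidecar recording the run configuration.
#'
#' @param maps A `parameter_maps` object (e.g. from [wt2_fit()]).
#' @param out_dir Output directory (created if missing).
#' @param config Named list of run settings stored in the sidecar (grid,
#'   fat T2, method, echo count, seed, ...). The package version is added.
#'
#' @return Invisibly, the vector of written file paths.
#' @export
write_maps <- function(maps, out_dir, config = list()) {
  stopifnot(inherits(maps, "parameter_maps"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(wt2 = "wt2_ms.nii.gz", ff = "ff_fraction.nii.gz",
             b1 = "b1_fraction.nii.gz", correlation = "correlation.nii.gz")
  paths <- character(0)
  for (name in names(files)) {
    p <- file.path(out_dir, files[[name]])
    write_nifti_map(maps[[name]], maps$affine, p)
    paths <- c(paths, p)
  }
  config$software_version <- as.character(utils::packageVersion("muscleWT2"))
  sidecar <- file.path(out_dir, "run_info.json")
  jsonlite::write_json(config, sidecar, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(c(paths, sidecar))
}

#' Read back a parameter map written by [write_maps()]
#'
#' @param path NIfTI path.
#' @return List with `values` (array) and `affine`.
#' @export
read_map <- function(path) {
  img <- RNifti::readNifti(path)
  vals <- as.array(img)
  if (length(dim(vals)) == 2L) dim(vals) <- c(dim(vals), 1L)  # single slice
  list(values = vals, affine = nifti_affine(img))
}
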