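# Extended phase graph (EPG) simulation of CPMG echo trains.
#
# The EPG formalism tracks magnetization as complex configuration states:
# transverse F+k / F-k and longitudinal Zk, indexed by the dephasing order k.
# RF pulses mix states within each order, relaxation scales them, and crusher
# gradients shift the transverse orders. We adopt the common bookkeeping in
# which the stored F- states are the complex conjugates of the physical F_{-k}
# so that a single 3x3 rotation matrix applies uniformly to all orders.
#
# Convention pinned here (and verified against an isochromat Bloch oracle in
# the tests): one unit of configuration-order shift per half echo-spacing
# (crushers flanking each refocusing pulse), excitation about x, refocusing
# about y (CPMG), echo amplitude = |F0| at the echo center.

#' Create an EPG state
#'
#' @param max_order Highest configuration order K tracked. Orders are
#'   0..K for `f_plus` and `z`, and the stored `f_minus` holds the complex
#'   conjugates of F_{-0}..F_{-K}.
#' @param equilibrium If `TRUE`, initialize to thermal equilibrium
#'   (`z[0] = m0`, all else zero); otherwise all states are zero.
#' @param m0 Equilibrium magnetization (fraction, default 1).
#'
#' @return An object of class `epg_state` with complex vectors `f_plus`,
#'   `f_minus`, `z` (length `max_order + 1`) and `max_order`.
#' @export
epg_state <- function(max_order, equilibrium = TRUE, m0 = 1) {
  max_order <- as.integer(max_order)
  stopifnot(max_order >= 1L)
  n <- max_order + 1L
  z <- complex(n)
  if (equilibrium) z[1] <- m0 + 0i
  structure(list(
    f_plus = complex(n),
    f_minus = complex(n),
    z = z,
    max_order = max_order
  ), class = "epg_state")
}

# 3x3 EPG rotation coefficients for a pulse of the given flip (radians) about
# an axis in the transverse plane at angle `phase` from x. Flip may be a
# vector; each coefficient is then a vector.
epg_rotation_coefs <- function(flip, phase) {
  ca2 <- cos(flip / 2)^2
  sa2 <- sin(flip / 2)^2
  sa <- sin(flip)
  ep <- exp(1i * phase)
  list(
    r11 = ca2 + 0i,            r12 = ep^2 * sa2,          r13 = -1i * ep * sa,
    r21 = Conj(ep)^2 * sa2,    r22 = ca2 + 0i,            r23 = 1i * Conj(ep) * sa,
    r31 = -0.5i * Conj(ep) * sa, r32 = 0.5i * ep * sa,    r33 = cos(flip) + 0i
  )
}

#' Apply an RF rotation to an EPG state
#'
#' Mixes `f_plus`, `f_minus` and `z` order-by-order through the standard EPG
#' rotation operator for a pulse with the given flip angle and phase.
#'
#' @param state An [epg_state()].
#' @param flip Flip angle in radians.
#' @param phase Pulse phase in radians (0 = rotation about x, `pi/2` = about
#'   y, the CPMG refocusing phase).
#'
#' @return The rotated `epg_state`.
#' @export
rf_rotation <- function(state, flip, phase = 0) {
  stopifnot(inherits(state, "epg_state"), is.finite(flip), is.finite(phase))
  r <- epg_rotation_coefs(flip, phase)
  fp <- state$f_plus; fm <- state$f_minus; z <- state$z
  state$f_plus  <- r$r11 * fp + r$r12 * fm + r$r13 * z
  state$f_minus <- r$r21 * fp + r$r22 * fm + r$r23 * z
  state$z       <- r$r31 * fp + r$r32 * fm + r$r33 * z
  state
}

#' Relax an EPG state and apply one unit of gradient dephasing
#'
#' Transverse states decay with `exp(-duration/t2)`, longitudinal states with
#' `exp(-duration/t1)` while `z[0]` regrows toward `m0`. The crusher shift
#' moves every transverse order up by one: F_k becomes F_{k+1}, so `f_plus`
#' shifts up, the stored `f_minus` shifts down, and the new F_0 is repopulated
#' from the former F_{-1}.
#'
#' @param state An [epg_state()].
#' @param duration Interval duration in ms (>= 0).
#' @param relax A [relaxation_params()] object.
#' @param m0 Equilibrium magnetization the longitudinal state regrows toward.
#'
#' @return The evolved `epg_state`.
#' @export
relax_and_shift <- function(state, duration, relax, m0 = 1) {
  stopifnot(inherits(state, "epg_state"), inherits(relax, "relaxation_params"))
  if (duration < 0) stop("duration must be >= 0")
  n <- state$max_order + 1L
  if (Mod(state$f_plus[n]) > 0 || Mod(state$f_minus[n]) > 0)
    stop("configuration order overflow: increase max_order")
  e2 <- exp(-duration / relax$t2)
  e1 <- exp(-duration / relax$t1)
  fp <- state$f_plus * e2
  fm <- state$f_minus * e2
  z <- state$z * e1
  z[1] <- z[1] + m0 * (1 - e1)
  # shift: F+ up, stored F- down, F_0 from the conjugate of the new F-(0)
  fp[2:n] <- fp[1:(n - 1L)]
  fm[1:(n - 1L)] <- fm[2:n]
  fm[n] <- 0i
  fp[1] <- Conj(fm[1])
  state$f_plus <- fp
  state$f_minus <- fm
  state$z <- z
  state
}

# Vectorized EPG CPMG engine. Simulates M independent echo trains at once.
# t1, t2, exc_flip: vectors of length M (radians for flips);
# ref_flip: length-M vector (constant over the train) or M x n_echoes matrix.
# Returns an M x n_echoes matrix of echo magnitudes (|F0| at echo centers).
epg_cpmg_engine <- function(t1, t2, exc_flip, ref_flip, n_echoes, echo_spacing,
                            m0 = 1) {
  m <- length(t2)
  stopifnot(length(t1) == m, length(exc_flip) == m)
  if (is.matrix(ref_flip)) {
    stopifnot(nrow(ref_flip) == m, ncol(ref_flip) == n_echoes)
  } else {
    stopifnot(length(ref_flip) == m)
    ref_flip <- matrix(ref_flip, m, n_echoes)
  }
  k <- 2L * n_echoes + 1L          # max order; overflow impossible
  nc <- k + 1L
  fp <- matrix(0i, m, nc)
  fm <- matrix(0i, m, nc)
  z <- matrix(0i, m, nc)
  z[, 1] <- m0 + 0i

  e2h <- exp(-echo_spacing / 2 / t2)
  e1h <- exp(-echo_spacing / 2 / t1)
  rec <- m0 * (1 - e1h)

  rot <- function(flip, phase) {
    r <- epg_rotation_coefs(flip, phase)
    # length-m coefficients recycle down the rows (column-major)
    fp2 <- r$r11 * fp + r$r12 * fm + r$r13 * z
    fm2 <- r$r21 * fp + r$r22 * fm + r$r23 * z
    z2 <- r$r31 * fp + r$r32 * fm + r$r33 * z
    fp <<- fp2; fm <<- fm2; z <<- z2
  }
  relax_shift_half <- function() {
    fp <<- fp * e2h
    fm <<- fm * e2h
    z <<- z * e1h
    z[, 1] <<- z[, 1] + rec
    fp[, 2:nc] <<- fp[, 1:(nc - 1L)]
    fm[, 1:(nc - 1L)] <<- fm[, 2:nc]
    fm[, nc] <<- 0i
    fp[, 1] <<- Conj(fm[, 1])
  }

  echoes <- matrix(0, m, n_echoes)
  rot(exc_flip, 0)                  # excitation about x
  for (e in seq_len(n_echoes)) {
    relax_shift_half()
    rot(ref_flip[, e], pi / 2)      # refocusing about y (CPMG)
    relax_shift_half()
    echoes[, e] <- Mod(fp[, 1])
  }
  echoes
}

#' Simulate a CPMG echo train for one tissue compartment
#'
#' Runs the EPG simulation of a multi-echo spin-echo train: excitation,
#' then per echo a half-interval of relaxation and dephasing, the refocusing
#' pulse (CPMG phase), another half interval, and readout of `|F0|`.
#'
#' @param relax A [relaxation_params()] object.
#' @param seq A [sequence_params()] object.
#' @param exc_flip Excitation flip angle in radians (default `pi/2`).
#' @param ref_flips Refocusing flip angles in radians, one per echo, or a
#'   single value recycled over the train. Defaults to the sequence's nominal
#'   refocusing flip.
#'
#' @return Numeric vector of echo amplitudes (fraction of M0), one per echo.
#' @examples
#' seq <- sequence_params()
#' # perfect refocusing: pure exp(-TE/T2) decay, independent of T1
#' tr <- epg_cpmg(relaxation_params(1400, 50), seq)
#' all.equal(tr, exp(-echo_times(seq) / 50))
#' @export
epg_cpmg <- function(relax, seq, exc_flip = pi / 2, ref_flips = NULL) {
  stopifnot(inherits(relax, "relaxation_params"), inherits(seq, "sequence_params"))
  if (is.null(ref_flips)) ref_flips <- seq$refocusing_flip * pi / 180
  if (length(ref_flips) == 1L) ref_flips <- rep(ref_flips, seq$n_echoes)
  if (length(ref_flips) != seq$n_echoes)
    stop("ref_flips must have one value per echo")
  drop(epg_cpmg_engine(relax$t1, relax$t2, exc_flip,
                       matrix(ref_flips, 1L), seq$n_echoes, seq$echo_spacing))
}

# Simulate echo trains for many voxels of the two-compartment water+fat model
# at once. wt2, ff, b1 are equal-length vectors; returns n_echoes x N matrix.
# Water and fat compartment trains are computed once per unique (T2, B1)
# combination, slice-profile averaged, and mixed per voxel.
epg_voxel_trains <- function(wt2, ff, b1, seq, profile,
                             fat_t2 = 151, t1_water = 1400, t1_fat = 365,
                             chunk_size = 16384L) {
  n <- length(wt2)
  stopifnot(length(ff) == n, length(b1) == n)
  if (any(ff < 0 | ff > 1)) stop("ff must lie in [0, 1]")
  if (any(b1 <= 0)) stop("b1 must be positive")
  profile <- validate_profile(profile)
  npos <- length(profile$positions)

  run_compartment <- function(t1, t2_vec, b1_vec) {
    # t2_vec, b1_vec: one entry per unique combo; expand over slice positions
    nu <- length(t2_vec)
    t2e <- rep(t2_vec, each = npos)
    b1e <- rep(b1_vec, each = npos)
    exc <- rep(profile$exc_flip, times = nu) * b1e
    ref <- rep(profile$ref_flip, times = nu) * b1e
    m <- nu * npos
    out <- matrix(0, m, seq$n_echoes)
    for (i0 in seq.int(1L, m, by = chunk_size)) {
      i1 <- min(i0 + chunk_size - 1L, m)
      idx <- i0:i1
      out[idx, ] <- epg_cpmg_engine(rep(t1, length(idx)), t2e[idx], exc[idx],
                                    ref[idx], seq$n_echoes, seq$echo_spacing)
    }
    # unweighted average across slice positions
    grp <- rep(seq_len(nu), each = npos)
    rowsum(out, grp) / npos           # nu x n_echoes
  }

  # water: unique (wT2, B1) pairs
  wkey <- paste(wt2, b1)
  wu <- !duplicated(wkey)
  wmap <- match(wkey, wkey[wu])
  W <- run_compartment(t1_water, wt2[wu], b1[wu])
  # fat: unique B1 only (fixed fat T2)
  fu <- !duplicated(b1)
  fmap <- match(b1, b1[fu])
  Ftr <- run_compartment(t1_fat, rep(fat_t2, sum(fu)), b1[fu])

  sat_w <- if (isTRUE(seq$apply_tr_saturation)) 1 - exp(-seq$tr / t1_water) else 1
  sat_f <- if (isTRUE(seq$apply_tr_saturation)) 1 - exp(-seq$tr / t1_fat) else 1

  sig <- (1 - ff) * sat_w * W[wmap, , drop = FALSE] +
    ff * sat_f * Ftr[fmap, , drop = FALSE]
  dimnames(sig) <- NULL
  t(sig)
}

#' Simulate the MESE signal of a voxel containing water and fat
#'
#' Two-compartment forward model: the voxel signal is the fat-fraction
#' weighted sum of a water echo train (T1 = `t1_water`, T2 = `wt2`) and a
#' single-peak fat train (T1 = `t1_fat`, T2 = `fat_t2`), each simulated with
#' the EPG formalism and averaged over the slice profile, with the B1 factor
#' scaling every flip angle. If `seq$apply_tr_saturation` is `TRUE` each
#' compartment is additionally scaled by `1 - exp(-TR/T1)`.
#'
#' @param wt2 Water T2 in ms.
#' @param ff Fat fraction in `[0, 1]`.
#' @param b1 B1 inhomogeneity factor (> 0); multiplies both the excitation
#'   and the refocusing flip angles.
#' @param seq A [sequence_params()] object.
#' @param profile A slice-profile table (see [build_profile_table()] or
#'   [hard_pulse_profile()]).
#' @param fat_t2 Fat T2 in ms (default 151).
#' @param t1_water,t1_fat Fixed compartment T1 values in ms (defaults 1400
#'   and 365).
#'
#' @return Numeric vector of echo amplitudes (fraction of M0).
#' @export
simulate_voxel_signal <- function(wt2, ff, b1, seq, profile, fat_t2 = 151,
                                  t1_water = 1400, t1_fat = 365) {
  stopifnot(length(wt2) == 1, length(ff) == 1, length(b1) == 1)
  if (ff < 0 || ff > 1) stop("ff must lie in [0, 1]")
  drop(epg_voxel_trains(wt2, ff, b1, seq, profile, fat_t2 = fat_t2,
                        t1_water = t1_water, t1_fat = t1_fat))
}
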