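# Independent oracles used across the suite.

# Brute-force isochromat Bloch simulation of a CPMG train: a set of spins
# uniformly spanning 2*pi of crusher dephasing per half echo-spacing, evolved
# with explicit 3x3 rotation/relaxation matrices; the echo amplitude is the
# magnitude of the complex mean transverse magnetization at the echo center.
# Entirely independent of the EPG configuration-state bookkeeping.
bloch_cpmg <- function(t1, t2, exc_flip, ref_flip, n_echoes, echo_spacing,
                       n_iso = 256) {
  phs <- 2 * pi * (seq_len(n_iso) - 0.5) / n_iso
  M <- rbind(0, 0, rep(1, n_iso))
  rotx <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
  roty <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
  relax <- function(M, dt) {
    e2 <- exp(-dt / t2); e1 <- exp(-dt / t1)
    M[1, ] <- M[1, ] * e2
    M[2, ] <- M[2, ] * e2
    M[3, ] <- M[3, ] * e1 + (1 - e1)
    M
  }
  dephase <- function(M) {
    mx <- M[1, ] * cos(phs) - M[2, ] * sin(phs)
    my <- M[1, ] * sin(phs) + M[2, ] * cos(phs)
    M[1, ] <- mx; M[2, ] <- my
    M
  }
  M <- rotx(exc_flip) %*% M
  out <- numeric(n_echoes)
  for (e in seq_len(n_echoes)) {
    M <- dephase(relax(M, echo_spacing / 2))
    M <- roty(ref_flip) %*% M
    M <- dephase(relax(M, echo_spacing / 2))
    out[e] <- Mod(mean(complex(real = M[1, ], imaginary = M[2, ])))
  }
  out
}

# full width at half maximum by linear interpolation at the half-height
# crossings
fwhm <- function(pos, y) {
  h <- max(y) / 2
  above <- which(y >= h)
  lo <- above[1]; hi <- above[length(above)]
  x1 <- if (lo == 1) pos[1] else
    pos[lo - 1] + (h - y[lo - 1]) / (y[lo] - y[lo - 1]) * (pos[lo] - pos[lo - 1])
  x2 <- if (hi == length(y)) pos[hi] else
    pos[hi] + (h - y[hi]) / (y[hi + 1] - y[hi]) * (pos[hi + 1] - pos[hi])
  x2 - x1
}

# small reusable fixtures
tiny_grid <- function() wt2_grid(wt2 = seq(25, 55, length.out = 10),
                                 ff = seq(0, 1, length.out = 6),
                                 b1 = c(0.8, 1.0, 1.2))
tiny_profile <- function(n = 8) build_profile_table(n_positions = n)
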