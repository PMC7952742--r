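# EPG operators and CPMG echo-train simulation.

test_that("rf_rotation: identity, excitation and perfect refocusing behave", {
  st <- epg_state(4)
  expect_equal(rf_rotation(st, 0, 0), st)

  # 90 deg about x on equilibrium: all magnetization becomes transverse
  ex <- rf_rotation(epg_state(4), pi / 2, 0)
  expect_equal(Mod(ex$f_plus[1]), 1, tolerance = 1e-12)
  expect_lt(Mod(ex$z[1]), 1e-12)

  # pi pulse with CPMG phase on a pure F+1 state: the amplitude moves to the
  # stored conjugate transverse line, longitudinal signs invert
  st <- epg_state(4, equilibrium = FALSE)
  st$f_plus[2] <- 1 + 0i
  st$z[1] <- 0.5 + 0i
  rot <- rf_rotation(st, pi, pi / 2)
  expect_equal(Mod(rot$f_minus[2]), 1, tolerance = 1e-12)
  expect_lt(Mod(rot$f_plus[2]), 1e-12)
  expect_equal(rot$z[1], -0.5 + 0i, tolerance = 1e-12)
})

test_that("relax_and_shift scales, shifts and regrows as advertised", {
  relax_none <- relaxation_params(1e12, 1e12)
  st <- rf_rotation(epg_state(6), pi / 2, 0)
  st$z[2] <- 0.3 + 0i
  ev <- relax_and_shift(st, 0, relaxation_params(1400, 50))
  # duration 0: pure shift, amplitude magnitudes preserved
  expect_equal(Mod(ev$f_plus[2]), Mod(st$f_plus[1]), tolerance = 1e-15)
  expect_equal(ev$z, st$z)

  # quasi-infinite relaxation times: magnitudes preserved over any duration
  ev2 <- relax_and_shift(st, 123.4, relax_none)
  expect_equal(Mod(ev2$f_plus[2]), Mod(st$f_plus[1]), tolerance = 1e-9)

  # finite T2: transverse amplitudes scaled by exp(-duration/t2)
  ev3 <- relax_and_shift(st, 5.45, relaxation_params(1400, 50))
  expect_equal(Mod(ev3$f_plus[2]), Mod(st$f_plus[1]) * exp(-5.45 / 50),
               tolerance = 1e-12)

  # T1 recovery of z0 toward m0
  st0 <- epg_state(4, equilibrium = FALSE)
  ev4 <- relax_and_shift(st0, 700, relaxation_params(1400, 50))
  expect_equal(Re(ev4$z[1]), 1 - exp(-700 / 1400), tolerance = 1e-12)

  # order overflow raises
  stov <- epg_state(2, equilibrium = FALSE)
  stov$f_plus[3] <- 1 + 0i
  expect_error(relax_and_shift(stov, 1, relaxation_params(1400, 50)),
               "overflow")
})

test_that("epg_cpmg equals the manual composition of the state operators", {
  seqp <- sequence_params(n_echoes = 6, echo_spacing = 12, tr = 2000)
  relax <- relaxation_params(1000, 60)
  ref <- 0.75 * pi
  train <- epg_cpmg(relax, seqp, ref_flips = ref)

  st <- rf_rotation(epg_state(2 * 6 + 1), pi / 2, 0)
  manual <- numeric(6)
  for (e in 1:6) {
    st <- relax_and_shift(st, 6, relax)
    st <- rf_rotation(st, ref, pi / 2)
    st <- relax_and_shift(st, 6, relax)
    manual[e] <- Mod(st$f_plus[1])
  }
  expect_equal(train, manual, tolerance = 1e-14)
})

test_that("perfect refocusing gives exp(-n*esp/T2), independent of T1", {
  for (t2 in c(20, 35, 50, 65, 80)) {
    for (esp in c(5, 10.9, 20)) {
      seqp <- sequence_params(n_echoes = 17, echo_spacing = esp, tr = 4100)
      tr1 <- epg_cpmg(relaxation_params(1400, t2), seqp)
      expect_lt(max(abs(tr1 - exp(-seq_len(17) * esp / t2))), 1e-9)
      tr2 <- epg_cpmg(relaxation_params(250, t2), seqp)
      expect_lt(max(abs(tr1 - tr2)), 1e-12)
    }
  }
  # no-relaxation limit: all echoes at unity
  seqp <- sequence_params()
  trinf <- epg_cpmg(relaxation_params(1e12, 1e12), seqp)
  expect_equal(trinf, rep(1, 17), tolerance = 1e-9)
})

test_that("EPG matches the isochromat Bloch oracle for imperfect refocusing", {
  seqp <- sequence_params()
  for (flip in c(0.4, 0.8, 1.1, 1.4) * pi) {
    for (t2 in c(30, 150)) {
      epg <- epg_cpmg(relaxation_params(1400, t2), seqp,
                      exc_flip = pi / 2, ref_flips = flip)
      oracle <- bloch_cpmg(1400, t2, pi / 2, flip, 17, 10.9)
      expect_lt(max(abs(epg - oracle)), 1e-6)
    }
  }
})

test_that("stimulated echoes prolong the apparent decay below 180 degrees", {
  seqp <- sequence_params()
  te <- echo_times(seqp)
  for (b1 in c(0.7, 0.8, 0.9)) {
    tr <- epg_cpmg(relaxation_params(1400, 50), seqp, exc_flip = b1 * pi / 2,
                   ref_flips = b1 * pi)
    # normalized to the first echo (the B1-scaled excitation attenuates the
    # whole train): even echoes carry the stimulated-echo surplus over the
    # pure-exponential envelope, while odd echoes oscillate below it, the
    # CPMG hallmark pinned by the Bloch oracle above
    ratio <- (tr / tr[1]) / exp(-(te - te[1]) / 50)
    even <- seq(2, 16, by = 2)
    expect_true(all(ratio[even] >= 1 - 1e-9))
    expect_gt(max(ratio), 1)
    # the train as a whole decays slower than exp(-t/T2)
    fit <- fit_monoexponential(tr, te)
    expect_gt(fit$t2, 50)
  }
})

test_that("echo amplitudes are non-decreasing in T2", {
  seqp <- sequence_params(n_echoes = 10)
  t2s <- c(25, 35, 50, 70, 80)
  for (flip in c(0.7 * pi, pi)) {
    trains <- sapply(t2s, function(t2)
      epg_cpmg(relaxation_params(1400, t2), seqp, ref_flips = flip))
    diffs <- t(apply(trains, 1, diff))
    expect_true(all(diffs >= -1e-12))
  }
})

test_that("simulate_voxel_signal mixes compartments linearly with TR saturation", {
  seqp <- sequence_params()
  prof <- tiny_profile()
  w <- simulate_voxel_signal(45, 0, 1, seqp, prof)
  f <- simulate_voxel_signal(45, 1, 1, seqp, prof)
  half <- simulate_voxel_signal(45, 0.5, 1, seqp, prof)
  expect_equal(half, 0.5 * w + 0.5 * f, tolerance = 1e-12)
  # ff = 1: independent of wT2
  f2 <- simulate_voxel_signal(22, 1, 1, seqp, prof)
  expect_equal(f, f2, tolerance = 1e-14)
  # TR saturation scales each compartment by 1 - exp(-TR/T1)
  seq_nosat <- sequence_params(apply_tr_saturation = FALSE)
  w0 <- simulate_voxel_signal(45, 0, 1, seq_nosat, prof)
  expect_equal(w, w0 * (1 - exp(-4100 / 1400)), tolerance = 1e-12)
  expect_error(simulate_voxel_signal(45, 1.2, 1, seqp, prof), "ff")
})

test_that("a degenerate rectangular profile collapses to the hard-pulse train", {
  seqp <- sequence_params(apply_tr_saturation = FALSE)
  s <- simulate_voxel_signal(50, 0, 1, seqp, hard_pulse_profile())
  expect_equal(s, epg_cpmg(relaxation_params(1400, 50), seqp),
               tolerance = 1e-12)
})
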