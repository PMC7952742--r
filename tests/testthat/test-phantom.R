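# Digital phantom generation.

test_that("noiseless phantom equals the forward model and is deterministic", {
  seqp <- sequence_params(n_echoes = 7)
  prof <- tiny_profile()
  spec <- phantom_spec(shape = c(24, 24, 2), noise_sigma = 0)
  ph <- make_phantom(spec, seqp, prof)

  fg <- which(ph$labels > 0)
  picks <- fg[round(seq(1, length(fg), length.out = 12))]
  for (v in picks) {
    idx <- arrayInd(v, dim(ph$labels))
    sig <- ph$mese$volume[idx[1], idx[2], idx[3], ]
    expected <- simulate_voxel_signal(ph$wt2_true[v], ph$ff_true[v],
                                      ph$b1_true[v], seqp, prof)
    expect_equal(sig, expected, tolerance = 1e-12)
  }
  expect_true(all(ph$mese$volume[, , , 1][ph$labels == 0] == 0))

  spec_n <- phantom_spec(shape = c(24, 24, 2), noise_sigma = 0.02, seed = 9L)
  ph1 <- make_phantom(spec_n, seqp, prof)
  ph2 <- make_phantom(spec_n, seqp, prof)
  expect_identical(ph1$mese$volume, ph2$mese$volume)
  ph3 <- make_phantom(phantom_spec(shape = c(24, 24, 2), noise_sigma = 0.02,
                                   seed = 10L), seqp, prof)
  expect_false(identical(ph1$mese$volume, ph3$mese$volume))
})

test_that("background noise follows the Rayleigh limit of the Rician model", {
  seqp <- sequence_params(n_echoes = 4)
  spec <- phantom_spec(shape = c(64, 64, 2), noise_sigma = 0.02, seed = 5L)
  ph <- make_phantom(spec, seqp, hard_pulse_profile())
  bg_sel <- array(ph$labels == 0, dim = dim(ph$mese$volume))
  bg <- ph$mese$volume[bg_sel]
  expect_gt(length(bg), 1e4)
  expect_equal(mean(bg), ph$noise_sd * sqrt(pi / 2), tolerance = 0.05)

  # gaussian alternative: zero-mean background
  specg <- phantom_spec(shape = c(64, 64, 2), noise_sigma = 0.02, seed = 5L,
                        noise_model = "gaussian")
  phg <- make_phantom(specg, seqp, hard_pulse_profile())
  bgg <- phg$mese$volume[, , , 1][phg$labels == 0]
  expect_lt(abs(mean(bgg)), 3 * ph$noise_sd / sqrt(length(bgg)) + 1e-4)
})

test_that("overlapping regions resolve last-listed-wins", {
  regions <- list(
    list(center = c(0.5, 0.5), radii = c(0.3, 0.3), wt2 = 30, ff = 0.1),
    list(center = c(0.5, 0.5), radii = c(0.15, 0.15), wt2 = 50, ff = 0.5))
  ph <- make_phantom(phantom_spec(shape = c(32, 32, 1), regions = regions,
                                  noise_sigma = 0),
                     sequence_params(n_echoes = 3), hard_pulse_profile())
  expect_equal(ph$wt2_true[16, 16, 1], 50)
  expect_equal(ph$labels[16, 16, 1], 2L)
  expect_equal(ph$wt2_true[16, 8, 1], 30)
})

test_that("the fat-fraction volume carries the requested affine shift", {
  spec <- phantom_spec(shape = c(16, 16, 1), noise_sigma = 0,
                       ff_map_shift = c(1, 0, 0))
  ph <- make_phantom(spec, sequence_params(n_echoes = 3), hard_pulse_profile())
  expect_equal(ph$ff_volume$affine[1, 4] - ph$mese$affine[1, 4],
               spec$voxel_size[1])
  expect_equal(ph$ff_volume$affine[2:3, 4], ph$mese$affine[2:3, 4])
})

test_that("phantom datasets round-trip through write_phantom and read_mese", {
  dir <- withr::local_tempdir()
  seqp <- sequence_params(n_echoes = 5)
  ph <- make_phantom(phantom_spec(shape = c(16, 16, 2), noise_sigma = 0.01),
                     seqp, hard_pulse_profile())
  write_phantom(ph, dir)
  mese <- read_mese(file.path(dir, "mese.nii.gz"))
  expect_equal(mese$echo_times, ph$mese$echo_times)
  expect_equal(mese$volume, ph$mese$volume, tolerance = 1e-6)
  truth <- read_map(file.path(dir, "truth_wt2_ms.nii.gz"))
  expect_equal(truth$values[!is.na(ph$wt2_true)],
               ph$wt2_true[!is.na(ph$wt2_true)], tolerance = 1e-6)
  spec_back <- jsonlite::fromJSON(file.path(dir, "phantom_spec.json"))
  expect_equal(spec_back$noise_sigma, 0.01)
})

test_that("noiseless end-to-end matching recovers truth within one grid step", {
  seqp <- sequence_params()
  spec <- phantom_spec(shape = c(24, 24, 1), noise_sigma = 0,
                       b1_field = "constant", b1_range = c(1, 1))
  ph <- make_phantom(spec, seqp, hard_pulse_profile())
  grid <- wt2_grid(wt2 = seq(20, 80, length.out = 60),
                   ff = seq(0, 1, length.out = 101), b1 = 1)
  fit <- wt2_fit(ph$mese, grid = grid, profile = hard_pulse_profile(),
                 seq = seqp)
  m <- ph$labels > 0
  expect_true(all(!is.na(fit$maps$wt2[m])))
  expect_lt(max(abs(fit$maps$wt2[m] - ph$wt2_true[m])),
            diff(grid$wt2[1:2]) + 1e-9)
  expect_lt(max(abs(fit$maps$ff[m] - ph$ff_true[m])),
            diff(grid$ff[1:2]) + 1e-9)
})
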