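# The wt2_fit modelling interface and the pipeline entry points.

test_that("wt2_fit returns a well-formed object with working methods", {
  seqp <- sequence_params(n_echoes = 7)
  ph <- make_phantom(phantom_spec(shape = c(16, 16, 1), noise_sigma = 0,
                                  b1_field = "constant", b1_range = c(1, 1)),
                     seqp, hard_pulse_profile())
  grid <- wt2_grid(wt2 = seq(20, 80, length.out = 31),
                   ff = seq(0, 1, length.out = 21), b1 = 1)
  fit <- wt2_fit(ph$mese, grid = grid, profile = hard_pulse_profile(),
                 seq = seqp)
  expect_s3_class(fit, "wt2_fit")
  expect_equal(dim(fit$maps$wt2), c(16, 16, 1))
  expect_true(all(is.na(fit$maps$wt2[ph$labels == 0])))
  expect_output(print(fit), "Water-T2 fit")
  sm <- summary(fit)
  expect_output(print(sm), "method epg")
  cf <- coef(fit)
  expect_named(cf, c("wt2", "ff", "b1", "correlation"))
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))

  expect_error(wt2_fit(ph$mese, echoes = 20), "only 7")
})

test_that("biexp and monoexp map fitting run voxelwise with constraints", {
  seqp <- sequence_params(n_echoes = 10, apply_tr_saturation = FALSE)
  ph <- make_phantom(phantom_spec(shape = c(10, 10, 1), noise_sigma = 0,
                                  b1_field = "constant", b1_range = c(1, 1)),
                     seqp, hard_pulse_profile())
  fit_b <- wt2_fit(ph$mese, method = "biexp", seq = seqp)
  m <- ph$labels > 0 & !is.na(fit_b$maps$wt2)
  # with perfect 180s the EPG forward model IS biexponential: near-exact fit
  expect_gt(sum(m), 10)
  expect_lt(median(abs(fit_b$maps$wt2[m] - ph$wt2_true[m])), 0.1)
  expect_lt(median(abs(fit_b$maps$ff[m] - ph$ff_true[m])), 0.01)

  # constrained biexp: ff fixed to the aligned truth
  fit_c <- wt2_fit(ph$mese, method = "biexp", ff = ph$ff_volume, seq = seqp)
  expect_equal(fit_c$maps$ff[m], ph$ff_true[m], tolerance = 1e-9)

  fit_m <- wt2_fit(ph$mese, method = "monoexp", seq = seqp)
  pure_water <- ph$labels > 0 & ph$ff_true == 0 & !is.na(fit_m$maps$wt2)
  expect_lt(median(abs(fit_m$maps$wt2[pure_water] - ph$wt2_true[pure_water])),
            0.1)
})

test_that("run_phantom and run_fit write readable, reproducible outputs", {
  dir <- withr::local_tempdir()
  pdir <- file.path(dir, "ph")
  cfg_ph <- list(output = pdir, seed = 11L, shape = c(16, 16, 1),
                 noise_sigma = 0.01, n_echoes = 5)
  run_phantom(cfg_ph)
  expect_true(file.exists(file.path(pdir, "mese.nii.gz")))
  expect_true(file.exists(file.path(pdir, "mese.json")))

  # determinism: same seed, same bytes in the data array
  pdir2 <- file.path(dir, "ph2")
  run_phantom(within(cfg_ph, output <- pdir2))
  v1 <- RNifti::readNifti(file.path(pdir, "mese.nii.gz"))
  v2 <- RNifti::readNifti(file.path(pdir2, "mese.nii.gz"))
  expect_identical(array(v1, dim = dim(v1)), array(v2, dim = dim(v2)))

  mdir <- file.path(dir, "maps")
  run_fit(list(input = file.path(pdir, "mese.nii.gz"), output = mdir,
               method = "epg", wt2_steps = 16, ff_steps = 11, b1_steps = 3,
               ff_map = file.path(pdir, "ff.nii.gz"), seed = 1L))
  for (f in c("wt2_ms.nii.gz", "ff_fraction.nii.gz", "b1_fraction.nii.gz",
              "correlation.nii.gz", "run_info.json"))
    expect_true(file.exists(file.path(mdir, f)))
  meta <- jsonlite::fromJSON(file.path(mdir, "run_info.json"))
  expect_equal(meta$fat_t2, 151)
  expect_true(meta$constrained)
  expect_error(run_fit(list(input = "x")), "config must")
})

test_that("run_stats produces one ROI row per label and the indicator table", {
  dir <- withr::local_tempdir()
  seqp <- sequence_params(n_echoes = 5)
  ph <- make_phantom(phantom_spec(shape = c(24, 24, 1), noise_sigma = 0.01),
                     seqp, hard_pulse_profile())
  mdir <- file.path(dir, "maps")
  fit <- wt2_fit(ph$mese, grid = wt2_grid(wt2 = seq(20, 80, length.out = 16),
                                          ff = seq(0, 1, length.out = 11),
                                          b1 = 1),
                 profile = hard_pulse_profile(), seq = seqp)
  write_maps(fit$maps, mdir)
  lab_path <- file.path(dir, "labels.nii.gz")
  muscleWT2:::write_nifti_map(ph$labels, ph$mese$affine, lab_path)

  subj_csv <- file.path(dir, "subjects.csv")
  write.csv(data.frame(subject = "s1", group = "control", maps_dir = mdir,
                       labels = lab_path, ff_ref = file.path(dir, "ph_ff.nii.gz")),
            subj_csv, row.names = FALSE)
  muscleWT2:::write_nifti_map(ph$ff_volume$values, ph$ff_volume$affine,
                              file.path(dir, "ph_ff.nii.gz"))
  out <- run_stats(list(subjects = subj_csv, output = file.path(dir, "stats")))
  expect_equal(nrow(out$roi_table), length(unique(ph$labels[ph$labels > 0])))
  expect_true(file.exists(file.path(dir, "stats", "roi_table.csv")))
  ind <- out$indicators
  expect_true("err_ff_pp" %in% ind$indicator)
  expect_true(all(is.finite(ind$value[ind$indicator == "pooled_sd_wt2_ms"])))
})
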