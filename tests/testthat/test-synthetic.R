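test_that("every generator is bit-reproducible for a fixed seed", {
  rc <- random_coil_table()
  tmpl <- abeta_fibril_template("wt", noise_sd_ppm = 0.3)
  expect_identical(gen_shift_table(tmpl, rc, seed = 7),
                   gen_shift_table(tmpl, rc, seed = 7))
  expect_identical(gen_dipshift_curve(0.5, noise_sd = 0.02, seed = 7),
                   gen_dipshift_curve(0.5, noise_sd = 0.02, seed = 7))
  expect_identical(gen_tht_trace(kinetics_preset(seed = 7)),
                   gen_tht_trace(kinetics_preset(seed = 7)))
  asg <- well_separated_assignments()
  spec <- data.frame(res_i = 19L, atom_i = "CB", res_j = 34L, atom_j = "CB")
  expect_identical(gen_peaklist(asg, spec, noise_sd = 0.05, seed = 7),
                   gen_peaklist(asg, spec, noise_sd = 0.05, seed = 7))
  pre <- diffraction_preset(noise_sd = 0.4)
  expect_identical(gen_xrd_profile(pre, seed = 7), gen_xrd_profile(pre, seed = 7))
  # different seeds produce different noise
  expect_false(identical(gen_xrd_profile(pre, seed = 7),
                         gen_xrd_profile(pre, seed = 8)))
})

test_that("generators leave the global RNG stream untouched", {
  set.seed(123)
  expected <- rnorm(3)
  set.seed(123)
  invisible(gen_tht_trace(kinetics_preset(seed = 99)))
  invisible(gen_dipshift_curve(0.4, noise_sd = 0.01, seed = 99))
  expect_identical(rnorm(3), expected)
})

test_that("an all-coil noiseless template reproduces the random-coil values exactly", {
  rc <- random_coil_table()
  seq <- abeta_sequence("wt")
  tmpl <- structure_template(seq, rep("coil", 40), noise_sd_ppm = 0)
  tab <- gen_shift_table(tmpl, rc, seed = 1)
  for (i in seq_len(nrow(tab))) {
    ref <- rc$shift_ppm[rc$res_type == tab$res_type[i] &
                          rc$nucleus == tab$nucleus[i]]
    expect_equal(tab$shift_ppm[i], ref)
  }
  # glycine rows never carry CB
  expect_false(any(tab$res_type == "G" & tab$nucleus == "CB"))
})

test_that("a noiseless beta template round-trips through classification", {
  rc <- random_coil_table()
  seq <- abeta_sequence("wt")
  tmpl <- structure_template(seq, rep("beta", 40), ca_offset_ppm = 2,
                             cb_offset_ppm = 2, noise_sd_ppm = 0)
  tab <- gen_shift_table(tmpl, rc, seed = 1)
  cls <- classify_ss(secondary_shift(tab, rc, quiet = TRUE))
  non_gly <- names(cls)[seq[as.integer(names(cls))] != "G"]
  expect_true(all(cls[non_gly] == "beta"))
})

test_that("unknown residue types are rejected by name unless skipping is requested", {
  rc <- random_coil_table()
  tmpl <- abeta_fibril_template("pglu3", noise_sd_ppm = 0)
  expect_error(gen_shift_table(tmpl, rc), "Z",
               class = "fibrilnmr_missing_reference")
  tab <- gen_shift_table(tmpl, rc, skip_missing = TRUE)
  expect_false(3L %in% tab$res_index) # pyroglutamate emits no rows
  expect_true(4L %in% tab$res_index)
})

test_that("noiseless generators equal their forward models exactly", {
  cv <- gen_dipshift_curve(0.5, noise_sd = 0, site = "x")
  fwd <- simulate_dephasing(0.5 / sqrt(3) * 22700, 5000, 16, site = "x")
  expect_identical(cv$intensity, fwd$intensity)
  zero <- gen_dipshift_curve(0, noise_sd = 0)
  expect_equal(zero$intensity, rep(1, 16))

  tr <- gen_tht_trace(kinetics_preset(noise_frac = 0))
  expect_equal(tr$intensity,
               1 + 10 / (1 + exp(-(tr$time_h - 13) / 3)))
})

test_that("noisy dipshift curves stay within the noise envelope of the noiseless model", {
  clean <- gen_dipshift_curve(0.5, noise_sd = 0)
  for (s in 1:2) {
    noisy <- gen_dipshift_curve(0.5, noise_sd = 0.02, seed = s)
    dev <- noisy$intensity - clean$intensity
    expect_lt(max(abs(dev)), 5 * 0.02)
    expect_gt(max(abs(dev)), 0)
  }
})

test_that("noisy ThT traces refit to within 5% of the generating parameters", {
  tr <- gen_tht_trace(kinetics_preset(t50_h = 13, tau_h = 3, noise_frac = 0.02,
                                      seed = 1))
  fit <- fit_tht(tr)
  expect_lt(abs(fit$t50_h - 13) / 13, 0.05)
  expect_lt(abs(fit$tau_h - 3) / 3, 0.05)
})

test_that("the mature contact preset round-trips to a mature stage call", {
  asg <- well_separated_assignments()
  mature <- data.frame(res_i = 19L, atom_i = "CB", res_j = 34L, atom_j = "CB")
  pk <- gen_peaklist(asg, mature, noise_sd = 0.05, seed = 12)
  expect_equal(classify_stage(detect_contacts(pk, asg))$stage, "mature")
})

test_that("the cross-beta preset round-trips to a positive cross-beta call", {
  prof <- gen_xrd_profile(diffraction_preset(noise_sd = 0.3), seed = 2)
  refl <- detect_reflections(prof)
  expect_true(classify_cross_beta(refl)$cross_beta)
})

test_that("shift tables round-trip through the TSV dialect", {
  rc <- random_coil_table()
  tab <- gen_shift_table(abeta_fibril_template("wt"), rc, seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_shift_table(tab, path)
  back <- read_shift_table(path)
  expect_equal(back$shift_ppm, tab$shift_ppm, tolerance = 1e-3)
  expect_equal(back$res_type, tab$res_type)
})

test_that("preset invariants are enforced", {
  expect_error(kinetics_preset(A = -1))
  expect_error(kinetics_preset(tau_h = 0))
  expect_error(kinetics_preset(time_h = c(0, 1, 1, 2)),
               class = "fibrilnmr_bad_input")
  expect_error(diffraction_preset(centers_deg = 50),
               class = "fibrilnmr_bad_input")
  expect_error(diffraction_preset(fwhm_deg = 0))
  expect_error(gen_dipshift_curve(1.2), class = "fibrilnmr_bad_input")
  expect_error(structure_template(abeta_sequence("wt"),
                                  rep("sheet", 40)),
               class = "fibrilnmr_bad_input")
})
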