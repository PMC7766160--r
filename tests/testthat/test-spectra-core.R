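test_that("inner-filter correction matches hand-evaluated values and inverts the forward attenuation", {
  expect_equal(correct_inner_filter(100, 0, 0), 100)
  expect_equal(correct_inner_filter(100, 0.2, 0.1), 100 * 10^(1.1 / 10),
               tolerance = 1e-12)
  expect_equal(correct_inner_filter(100, 0.2, 0.1), 128.825, tolerance = 1e-4)
  # strictly increasing in each absorbance
  expect_true(correct_inner_filter(100, 0.3, 0.1) >
                correct_inner_filter(100, 0.2, 0.1))
  expect_true(correct_inner_filter(100, 0.2, 0.2) >
                correct_inner_filter(100, 0.2, 0.1))
  expect_error(correct_inner_filter(-1, 0, 0), "domain")
  expect_error(correct_inner_filter(1, -0.1, 0), "domain")
  # exact inversion of the generator's forward attenuation over [0, 2]^2
  grid <- expand.grid(A_ex = seq(0, 2, by = 0.25), A_em = seq(0, 2, by = 0.25))
  F_true <- 812.5
  F_att <- fluorbind:::apply_inner_filter(F_true, grid$A_ex, grid$A_em)
  back <- correct_inner_filter(F_att, grid$A_ex, grid$A_em)
  expect_true(all(abs(back - F_true) / F_true < 1e-12))
})

test_that("band intensity reads the requested band", {
  sp1 <- emission_spectrum(330, 500)
  expect_equal(band_intensity(sp1, 330), 500)
  sp <- gaussian_spectrum()
  expect_gt(band_intensity(sp, 330, window = 10), band_intensity(sp, 360, window = 10))
  # analytic value at an off-center wavelength, nearest-point read
  expect_equal(band_intensity(sp, 342.4), 1000 * exp(-(342 - 330)^2 / (2 * 12.74^2)),
               tolerance = 1e-12)
  expect_error(band_intensity(sp, 500), "range")
})

test_that("band FWHM recovers 2*sqrt(2 ln 2)*sigma for Gaussian bands", {
  expect_equal(band_fwhm(gaussian_spectrum(sigma = 12.74), 330), 30.0,
               tolerance = 0.2 / 30)
  expect_equal(band_fwhm(gaussian_spectrum(center = 485, sigma = 19.53,
                                           wl = seq(400, 570, by = 1)), 485),
               46.0, tolerance = 0.2 / 46)
  flat <- emission_spectrum(seq(300, 400, by = 1), rep(100, 101))
  expect_error(band_fwhm(flat, 330), "unresolved")
})

test_that("delta_F is the absolute percent change and is scale invariant", {
  expect_equal(delta_F(100, 100), 0)
  expect_equal(delta_F(50, 100), 50)
  expect_equal(delta_F(130, 100), 30)
  expect_error(delta_F(50, 0), "domain")
  for (c_scale in c(0.01, 1, 250)) {
    expect_equal(delta_F(c_scale * 37, c_scale * 120), delta_F(37, 120))
  }
})

test_that("mean residue ellipticity applies the CD normalization and its homogeneities", {
  sp <- cd_spectrum(seq(200, 260, 10), rep(10, 7), protein_total = 4e-6,
                    path_length = 0.01, n_residues = 383)
  val <- mean_residue_ellipticity(sp)
  expect_equal(val, rep(10 / (10 * 4e-6 * 0.01 * 383), 7), tolerance = 1e-12)
  expect_equal(val[1], 65274, tolerance = 1e-4)
  zero <- sp; zero$theta_mdeg[] <- 0
  expect_equal(mean_residue_ellipticity(zero), rep(0, 7))
  double_p <- sp; double_p$protein_total <- 8e-6
  expect_equal(mean_residue_ellipticity(double_p), val / 2)
  double_theta <- sp; double_theta$theta_mdeg <- sp$theta_mdeg * 2
  expect_equal(mean_residue_ellipticity(double_theta), val * 2)
  bad <- sp; bad$protein_total <- 0
  expect_error(mean_residue_ellipticity(bad), "domain")
})

test_that("titration CSV round-trips exactly and converts declared units", {
  truth <- quiet_truth()
  series <- simulate_titration(truth, 4e-6, 288, seq(0, 20e-6, by = 0.5e-6))
  path <- tempfile(fileext = ".csv")
  write_titration(series, path)
  back <- read_titration(path)
  expect_identical(back$records$ligand_total, series$records$ligand_total)
  expect_identical(back$records$F_raw, series$records$F_raw)
  expect_identical(back$records$A_ex, series$records$A_ex)
  expect_equal(back$protein_total, series$protein_total)
  expect_equal(back$temperature, series$temperature)

  um_file <- tempfile(fileext = ".csv")
  writeLines(c("# protein_total: 4", "# temperature: 288", "# units: uM",
               "ligand_total,F_raw,A_ex,A_em",
               "0,1000,0,0", "1,900,0.01,0.004", "2,820,0.02,0.008"), um_file)
  um <- read_titration(um_file)
  expect_equal(um$protein_total, 4e-6)
  expect_equal(um$records$ligand_total, c(0, 1e-6, 2e-6))
})

test_that("titration reader rejects malformed files with actionable errors", {
  no_zero <- tempfile(fileext = ".csv")
  writeLines(c("# protein_total: 4e-6", "# temperature: 288", "# units: M",
               "ligand_total,F_raw,A_ex,A_em",
               "1e-6,900,0,0", "2e-6,820,0,0"), no_zero)
  expect_error(read_titration(no_zero), "ligand_total = 0")

  non_mono <- tempfile(fileext = ".csv")
  writeLines(c("# protein_total: 4e-6", "# temperature: 288", "# units: M",
               "ligand_total,F_raw,A_ex,A_em",
               "0,1000,0,0", "2e-6,820,0,0", "1e-6,900,0,0"), non_mono)
  expect_error(read_titration(non_mono), "row 3")

  missing_col <- tempfile(fileext = ".csv")
  writeLines(c("# protein_total: 4e-6", "# temperature: 288",
               "ligand_total,F_raw", "0,1000", "1e-6,900"), missing_col)
  expect_error(read_titration(missing_col), "A_ex")

  no_meta <- tempfile(fileext = ".csv")
  writeLines(c("ligand_total,F_raw,A_ex,A_em", "0,1000,0,0"), no_meta)
  expect_error(read_titration(no_meta), "protein_total")
})
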