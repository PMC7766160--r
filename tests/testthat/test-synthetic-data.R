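test_that("van't Hoff forward model and its round trip", {
  expect_equal(k_of_temperature(0, 0, c(250, 300, 350)), rep(1, 3))
  expect_equal(k_of_temperature(1e5, 400, 300), 3036.93, tolerance = 1e-5)
  temps <- c(288, 298, 308)
  K <- k_of_temperature(130.13e3, 539.46, temps)
  th <- fit_vant_hoff(data.frame(temperature = temps, K_a = K))
  expect_equal(th$delta_H, 130.13e3, tolerance = 1e-10)
  expect_equal(th$delta_S, 539.46, tolerance = 1e-10)
})

test_that("Adair isotherm limits and reductions", {
  expect_equal(adair_nu(0, 1e5, 50), 0)
  expect_equal(adair_nu(1e-5, 1e5, 1), 1)  # c = 1, KL = 1: half saturation
  expect_equal(adair_nu(1e-2, 1e5, 100), 2, tolerance = 1e-3)
  L <- 10^seq(-8, -3, length.out = 30)
  expect_equal(adair_nu(L, 2e5, 1), 2 * (2e5 * L) / (1 + 2e5 * L),
               tolerance = 1e-12)
  nu <- adair_nu(L, 1e5, 50)
  expect_true(all(nu >= 0 & nu < 2))
  expect_true(all(diff(nu) > 0))
})

test_that("free-ligand solver matches the independent quadratic oracle", {
  expect_equal(solve_free_ligand(4e-6, 0, 1e5, 50), 0)
  expect_equal(solve_free_ligand(4e-6, 7e-6, 0, 50), 7e-6)
  K <- 2.7e5
  for (P in c(1e-6, 4e-6, 8e-6)) {
    L_tot <- seq(0.5e-6, 20e-6, by = 0.5e-6)
    ours <- solve_free_ligand(P, L_tot, K, 1)
    oracle <- free_ligand_quadratic(P, L_tot, K)
    expect_true(all(abs(ours - oracle) / oracle < 1e-10))
  }
})

test_that("simulated titrations satisfy mass balance exactly before noise", {
  truth <- quiet_truth()
  P <- 6e-6
  L_tot <- seq(0, 20e-6, by = 0.5e-6)
  fp <- fluorbind:::forward_point(truth, P, L_tot, 288)
  resid <- abs(fp$L_free + fp$nu * P - L_tot)
  expect_true(all(resid <= 1e-12 * pmax(L_tot, 1e-12)))
})

test_that("titration simulator honours the quench law and inner-filter round trip", {
  no_quench <- quiet_truth(q_max = 1e-12)
  s <- simulate_titration(no_quench, 4e-6, 288, seq(0, 20e-6, by = 2e-6))
  Fc <- correct_series(s)$records$F_corr
  expect_lt(max(abs(Fc / Fc[1] - 1)), 1e-9)
  # raw/corrected differ exactly by the inner-filter factor
  att <- 10^(-(5 * s$records$A_ex + s$records$A_em) / 10)
  expect_equal(s$records$F_raw, Fc * att, tolerance = 1e-12)

  truth <- quiet_truth()
  s2 <- correct_series(simulate_titration(truth, 4e-6, 288,
                                          seq(0, 20e-6, by = 0.5e-6)))
  expect_equal(nrow(s2$records), 41)
  ratio <- s2$records$F_corr[1] / s2$records$F_corr
  expect_true(all(diff(ratio) > 0))

  expect_error(simulate_titration(truth, 4e-6, 288, c(1e-6, 2e-6)), "start at 0")
})

test_that("stochastic outputs are bit-reproducible given (seed, parameters)", {
  truth <- ground_truth(noise_rel = 0.01, seed = 33)
  a <- simulate_titration(truth, 4e-6, 288, seq(0, 10e-6, by = 1e-6))
  b <- simulate_titration(truth, 4e-6, 288, seq(0, 10e-6, by = 1e-6))
  expect_identical(a$records$F_raw, b$records$F_raw)
  other <- simulate_titration(truth, 4e-6, 288, seq(0, 10e-6, by = 1e-6),
                              seed_offset = 1)
  expect_false(identical(a$records$F_raw, other$records$F_raw))
  d1 <- simulate_decay(truth, 5e-6)
  d2 <- simulate_decay(truth, 5e-6)
  expect_identical(d1$counts, d2$counts)
})

test_that("decay simulator peak expectation and dynamic-regime lifetime scaling", {
  truth <- quiet_truth(seed = 12)
  reps <- vapply(1:40, function(i)
    simulate_decay(truth, 0, peak_counts = 1e4, seed_offset = i)$counts[1], 0)
  expect_equal(mean(reps), 1e4, tolerance = 0.01)
  f_ratio <- 0.7  # F/F0 in a collisional regime
  dyn <- simulate_decay(truth, 1e-5, peak_counts = 2e4, tau_scale = f_ratio,
                        seed_offset = 2)
  fit <- fit_decay(dyn)
  tau0 <- average_lifetime(truth$tau_components)
  expect_equal(tau0 / fit$tau_avg, 1 / f_ratio, tolerance = 0.02)
})

test_that("CD simulator interpolates structure fractions and inverts exactly", {
  truth <- quiet_truth()
  cds <- simulate_cd(truth, c(0, 5, 12.5))
  f0 <- fluorbind:::cd_fractions(truth, 0)
  expect_equal(unname(f0), c(0.34, 0.16, 0.20, 0.30), tolerance = 1e-12)
  for (r in c(0, 2.5, 7.5, 12.5)) {
    expect_equal(sum(fluorbind:::cd_fractions(truth, r)), 1, tolerance = 1e-12)
  }
  # mean_residue_ellipticity inverts the generator's mdeg conversion
  basis <- fluorbind:::cd_basis(cds[[2]]$wavelengths)
  expected_mre <- as.numeric(basis %*% fluorbind:::cd_fractions(truth, 5))
  expect_equal(mean_residue_ellipticity(cds[[2]]), expected_mre,
               tolerance = 1e-12)
})

test_that("simulated dataset assembles every modality with the truth retained", {
  truth <- ground_truth(seed = 4)
  ds <- simulate_dataset(truth,
                         ligand_grid = seq(0, 20e-6, by = 2e-6),
                         decay_ligands = c(0, 1e-5))
  expect_length(ds$titrations, 9)
  expect_length(ds$decays, 2)
  expect_length(ds$cd, 6)
  expect_identical(ds$truth$seed, truth$seed)
})
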