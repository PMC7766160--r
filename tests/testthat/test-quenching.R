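test_that("Stern-Volmer fit recovers the generative constant", {
  s <- sv_series(2.02e4)
  fit <- fit_stern_volmer(s)
  expect_equal(fit$K_SV, 2.02e4, tolerance = 1e-9)
  expect_equal(fit$intercept, 1, tolerance = 1e-9)
  expect_gt(fit$r_squared, 1 - 1e-12)

  flat <- sv_series(0)
  expect_equal(fit_stern_volmer(flat)$K_SV, 0, tolerance = 1e-9)

  noisy <- sv_series(2.02e4, noise_rel = 0.01, seed = 11)
  expect_equal(fit_stern_volmer(noisy)$K_SV, 2.02e4, tolerance = 0.05)

  short <- titration_series(4e-6, 298,
    data.frame(ligand_total = c(0, 1e-6, 2e-6), F_raw = c(100, 90, 80),
               A_ex = 0, A_em = 0))
  expect_error(fit_stern_volmer(short), "insufficient")
})

test_that("average lifetime is the intensity-weighted mean with its invariances", {
  expect_equal(average_lifetime(list(c(1, 2))), 2)
  expect_equal(average_lifetime(list(c(0.5, 1), c(0.5, 3))), 2.5)
  expect_error(average_lifetime(list()), "domain")
  comps <- list(c(0.2, 1.1), c(0.5, 2.7), c(0.3, 6.2))
  tau <- average_lifetime(comps)
  scaled <- lapply(comps, function(p) c(7.3 * p[1], p[2]))
  expect_equal(average_lifetime(scaled), tau)
  expect_gte(tau, 1.1)
  expect_lte(tau, 6.2)
})

test_that("decay fitting recovers mono- and bi-exponential truths and rejects flat traces", {
  truth <- ground_truth(tau_components = data.frame(alpha = 1, tau = 2.2),
                        seed = 5)
  tr <- simulate_decay(truth, n_channels = 256, dt = 0.05, peak_counts = 1e4)
  fit <- fit_decay(tr)
  expect_equal(fit$n_components, 1)
  expect_equal(fit$tau_avg, 2.2, tolerance = 0.02)

  truth2 <- ground_truth(tau_components = data.frame(alpha = c(0.5, 0.5),
                                                     tau = c(1, 3)), seed = 7)
  tr2 <- simulate_decay(truth2, n_channels = 512, dt = 0.05, peak_counts = 5e4)
  fit2 <- fit_decay(tr2)
  expect_equal(fit2$n_components, 2)
  expect_equal(fit2$components$tau[1], 1, tolerance = 0.05)
  expect_equal(fit2$components$tau[2], 3, tolerance = 0.05)
  expect_equal(sum(fit2$components$alpha), 1, tolerance = 1e-9)

  flat <- decay_trace(seq(0, by = 0.05, length.out = 100),
                      rep(50, 100))
  expect_error(fit_decay(flat), "no decaying signal")
})

test_that("bimolecular constant is K_SV/tau0 at the tabulated scales", {
  expect_equal(bimolecular_constant(2.02e4, 2.2e-9), 9.18e12, tolerance = 1e-3)
  expect_equal(bimolecular_constant(3.58e4, 2.2e-9), 1.627e13, tolerance = 1e-3)
  for (ksv in c(11, 2.02e4, 3.58e4)) {
    tau0 <- 2.2e-9
    expect_equal(bimolecular_constant(ksv, tau0) * tau0, ksv)
  }
  expect_error(bimolecular_constant(1e4, 0), "domain")
})

test_that("mechanism classifier separates static, dynamic and conflicting evidence", {
  tau0 <- 2.2
  static_decays <- lapply(c(0, 5e-6, 10e-6, 20e-6), function(L)
    list(tau_avg = tau0 * (1 + 1e-3), ligand_total = L))
  sv_rising <- lapply(c(288, 298, 308), function(Tk)
    structure(list(K_SV = 2.02e4 * (1 + (Tk - 288) / 40), temperature = Tk),
              class = "stern_volmer_fit"))
  out <- classify_mechanism(sv_rising, static_decays, tau0)
  expect_equal(out$mechanism, "static")
  expect_equal(out$ksv_temperature_trend, "increasing")
  expect_true(all(out$k_q_values > 1e10))

  # collisional regime: tau0/tau = F0/F with K_SV = k_q * tau0 = 11 M^-1,
  # observable only at mM quencher
  K_dyn <- 5e9 * tau0 * 1e-9
  Lmm <- c(0, 5e-3, 10e-3, 20e-3)
  dyn_decays <- lapply(Lmm, function(L)
    list(tau_avg = tau0 / (1 + K_dyn * L), ligand_total = L))
  sv_dyn <- lapply(c(288, 298, 308), function(Tk)
    structure(list(K_SV = K_dyn, temperature = Tk), class = "stern_volmer_fit"))
  out_dyn <- classify_mechanism(sv_dyn, dyn_decays, tau0)
  expect_equal(out_dyn$mechanism, "dynamic")

  # conflicting: lifetimes flat while K_SV (hence predicted F0/F) is large
  # but k_q is below the diffusion limit
  amb_decays <- lapply(Lmm, function(L)
    list(tau_avg = tau0, ligand_total = L))
  out_amb <- classify_mechanism(sv_dyn, amb_decays, tau0)
  expect_equal(out_amb$mechanism, "ambiguous")

  # missing lifetime data degrades to ambiguous with a reason
  out_na <- classify_mechanism(sv_rising, list(), tau0)
  expect_equal(out_na$mechanism, "ambiguous")
  expect_match(out_na$reason, "missing lifetime")
})

test_that("static-quenching simulations keep lifetimes flat while intensity halves", {
  truth <- quiet_truth()
  ligs <- seq(0, 20e-6, by = 5e-6)
  taus <- vapply(seq_along(ligs), function(i) {
    fit_decay(simulate_decay(truth, ligs[i], peak_counts = 1e4,
                             seed_offset = i))$tau_avg
  }, 0)
  expect_lt(max(abs(taus / taus[1] - 1)), 0.02)
  s <- correct_series(simulate_titration(truth, 4e-6, 288,
                                         seq(0, 20e-6, by = 0.5e-6)))
  Fc <- s$records$F_corr
  expect_gt((Fc[1] - min(Fc)) / Fc[1], 0.5)
})
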