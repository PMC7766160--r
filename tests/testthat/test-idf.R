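test_that("saturation fit recovers noiseless logistic parameters", {
  p_true <- c(floor = 2, ceiling = 78, mid = -5.6, s = 1.7)
  L <- 10^seq(-7, -4, length.out = 40)
  dF <- p_true["floor"] + (p_true["ceiling"] - p_true["floor"]) /
    (1 + 10^(p_true["s"] * (p_true["mid"] - log10(L))))
  curve <- fit_saturation(data.frame(ligand_total = L, deltaF = dF),
                          protein_total = 4e-6, asymmetry = 1)
  expect_equal(unname(curve$params[c("floor", "ceiling", "log10_midpoint",
                                     "steepness")]),
               unname(p_true), tolerance = 1e-6)
  expect_gt(curve$r_squared, 1 - 1e-10)

  expect_error(fit_saturation(data.frame(ligand_total = L[1:4], deltaF = dF[1:4]),
                              4e-6), "insufficient")
})

test_that("saturation fit describes simulated cooperative titrations", {
  truth <- quiet_truth()
  s <- correct_series(simulate_titration(truth, 4e-6, 288,
                                         seq(0, 20e-6, by = 0.5e-6)))
  Fc <- s$records$F_corr
  curve <- fit_saturation(data.frame(ligand_total = s$records$ligand_total,
                                     deltaF = delta_F(Fc, Fc[1])), 4e-6)
  expect_gt(curve$r_squared, 0.99)
})

test_that("saturation inversion round-trips and respects its range", {
  L <- 10^seq(-7, -4, length.out = 40)
  dF <- 5 + 70 / (1 + 10^(1.3 * (-5.5 - log10(L))))
  curve <- fit_saturation(data.frame(ligand_total = L, deltaF = dF), 4e-6,
                          asymmetry = 1)
  for (Lq in c(3e-6, 1e-5, 2e-5)) {
    expect_equal(invert_saturation(curve, predict(curve, Lq)), Lq,
                 tolerance = 1e-9)
  }
  # logistic symmetry: the midpoint deltaF inverts to the midpoint
  mid_dF <- (curve$params[["floor"]] + curve$params[["ceiling"]]) / 2
  expect_equal(log10(invert_saturation(curve, mid_dF)),
               curve$params[["log10_midpoint"]], tolerance = 1e-9)
  expect_error(invert_saturation(curve, 95), "range")
})

test_that("binding density extracts exact lines from consistent curves", {
  # curves built so the inverse at quench level g is L = ell(g) + 0.5 P:
  # slope must be exactly 0.5 at every level
  curves <- lapply(c(4e-6, 6e-6, 8e-6), function(P) {
    f <- function(L) { u <- (L - 0.5 * P) / 1e-6; 100 * u / (1 + u) }
    saturation_exact(f, P, ligand_range = c(0.5 * P + 1e-12, 1e-3))
  })
  bd <- binding_density(curves, deltaF_grid = c(30, 50, 60, 70, 80))
  expect_equal(bd$nu_total, rep(0.5, 5), tolerance = 1e-9)
  # at g = 50, u = 1, so the intercept is exactly 1e-6
  expect_equal(bd$L_free[bd$deltaF == 50], 1e-6, tolerance = 1e-9)
  expect_error(binding_density(curves[1]), "insufficient|curves")
})

test_that("binding density on noiseless cooperative curves matches the generative isotherm", {
  truth <- quiet_truth()
  curves <- adair_exact_curves(truth, c(4e-6, 6e-6, 8e-6), 288)
  bd <- binding_density(curves)
  K <- k_of_temperature(truth$delta_H, truth$delta_S, 288)
  nu_true <- adair_nu(bd$L_free, K, truth$coop_factor_c)
  expect_true(all(abs(bd$nu_total - nu_true) / nu_true < 0.02))
  # mass conservation: L_tot = L_free + nu P reproduces each inversion
  for (i in c(1, 8, 15)) {
    for (cv in curves) {
      L_tot <- invert_saturation(cv, bd$deltaF[i])
      expect_equal(bd$L_free[i] + bd$nu_total[i] * cv$protein_total, L_tot,
                   tolerance = 1e-9)
    }
  }
})

test_that("Scatchard concavity classifies cooperativity", {
  hill_points <- function(h, K = 2.67e5, n = 2, noise = 0.005, seed = 9) {
    L <- 10^seq(log10(1 / K) - 1.2, log10(1 / K) + 1.2, length.out = 12)
    nu <- n * (K * L)^h / (1 + (K * L)^h)
    nu <- withr_seed(seed, nu * (1 + rnorm(length(nu), 0, noise)))
    data.frame(deltaF = NA, nu_total = nu, L_free = L,
               stderr_nu = noise * nu, stderr_Lfree = 0,
               r_squared = 1, flagged = FALSE)
  }
  expect_equal(scatchard(hill_points(2.4))$classification, "positive_cooperativity")
  expect_equal(scatchard(hill_points(0.6))$classification, "negative_cooperativity")
  expect_equal(scatchard(hill_points(1))$classification, "noncooperative")
  too_few <- hill_points(1)[1:4, ]
  expect_error(scatchard(too_few), "insufficient")
})

test_that("Hill fit recovers generative parameters", {
  K <- 2.67e5; h_true <- 2.4; n_true <- 2
  L <- 10^seq(log10(1 / K) - 1, log10(1 / K) + 1, length.out = 20)
  nu <- n_true * (K * L)^h_true / (1 + (K * L)^h_true)
  pts <- data.frame(nu_total = nu, L_free = L)
  fit <- fit_hill(pts)
  expect_equal(fit$n_sites, n_true, tolerance = 0.01)
  expect_equal(fit$K_b, K, tolerance = 0.01)
  expect_equal(fit$h, h_true, tolerance = 0.01)

  # h = 1 reduces to the Langmuir isotherm with the generative K
  nu1 <- n_true * (K * L) / (1 + K * L)
  fit1 <- fit_hill(data.frame(nu_total = nu1, L_free = L))
  expect_equal(fit1$K_b, K, tolerance = 1e-4)
  expect_equal(fit1$h, 1, tolerance = 1e-4)

  # 2% noise, seed-pinned
  nu_noisy <- withr_seed(21, nu * (1 + rnorm(length(nu), 0, 0.02)))
  fitn <- fit_hill(data.frame(nu_total = nu_noisy, L_free = L,
                              stderr_nu = 0.02 * nu, stderr_Lfree = 0))
  expect_equal(fitn$h, h_true, tolerance = 0.15 / h_true)
  expect_equal(fitn$K_b, K, tolerance = 0.10)
})

test_that("Hill and Scatchard classifications agree across a cooperativity sweep", {
  truth_for <- function(cc) quiet_truth(coop_factor_c = cc)
  for (cc in c(1, 10, 50)) {
    truth <- truth_for(cc)
    curves <- adair_exact_curves(truth, c(4e-6, 6e-6, 8e-6), 288)
    bd <- binding_density(curves)
    hl <- fit_hill(bd)
    sc <- scatchard(bd)
    coop_hill <- classify_cooperativity(hl$h)
    agrees <- switch(sc$classification,
                     positive_cooperativity = coop_hill == "positive",
                     negative_cooperativity = coop_hill == "negative",
                     noncooperative = coop_hill == "noncooperative")
    expect_true(agrees, label = sprintf("c = %g: Hill %s vs Scatchard %s",
                                        cc, coop_hill, sc$classification))
    if (cc >= 10) expect_equal(coop_hill, "positive")
    if (cc == 1) expect_equal(coop_hill, "noncooperative")
  }
})

test_that("cooperativity thresholds on the Hill coefficient", {
  expect_equal(classify_cooperativity(2.4), "positive")
  expect_equal(classify_cooperativity(1.0), "noncooperative")
  expect_equal(classify_cooperativity(0.7), "negative")
  expect_equal(classify_cooperativity(1.05), "noncooperative")
  expect_error(classify_cooperativity(0), "domain")
})
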