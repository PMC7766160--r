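# Shared fixtures, all built in code.

# Binding constants at three temperatures as a binding study tabulates
# them (used by the thermodynamic tests).
ka_table <- data.frame(temperature = c(288, 298, 308),
                       K_a = c(8.82e5, 4.46e6, 3.0137e7))

# Noise-free ground truth for deterministic generator tests.
quiet_truth <- function(...) {
  args <- list(...)
  defaults <- list(noise_rel = 0, seed = 1L)
  do.call(ground_truth, modifyList(defaults, args))
}

# Titration series following the Stern-Volmer law exactly:
# F = F0 / (1 + K_SV * L), no absorbance.
sv_series <- function(K_SV, L = seq(0, 20e-6, by = 0.5e-6), F0 = 1000,
                      temperature = 298, noise_rel = 0, seed = 1) {
  Fv <- F0 / (1 + K_SV * L)
  if (noise_rel > 0) {
    Fv <- withr_seed(seed, Fv * (1 + rnorm(length(Fv), 0, noise_rel)))
  }
  correct_series(titration_series(4e-6, temperature,
    data.frame(ligand_total = L, F_raw = Fv, A_ex = 0, A_em = 0)))
}

# Minimal local stand-in for withr::with_seed (keeps the suite
# dependency-free): evaluates expr under a fixed seed, restoring the
# caller's RNG state.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Closed-form free-ligand solution for two independent sites (c = 1):
# L_tot = L + 2KL/(1+KL) * P  =>  K L^2 + (1 + 2KP - K L_tot) L - L_tot = 0.
free_ligand_quadratic <- function(P, L_tot, K) {
  vapply(L_tot, function(lt) {
    if (lt == 0) return(0)
    b <- 1 + 2 * K * P - K * lt
    (-b + sqrt(b^2 + 4 * K * lt)) / (2 * K)
  }, 0)
}

# Gaussian emission spectrum on a 1 nm grid.
gaussian_spectrum <- function(center = 330, sigma = 12.74, amplitude = 1000,
                              wl = seq(280, 420, by = 1)) {
  emission_spectrum(wl, amplitude * exp(-(wl - center)^2 / (2 * sigma^2)))
}

# Saturation curves from the noiseless Adair forward model, wrapped as
# exact curves (bisection inversion, no fitting error).
adair_exact_curves <- function(truth, protein_totals, temperature,
                               L_range = c(1e-9, 20e-6)) {
  K <- k_of_temperature(truth$delta_H, truth$delta_S, temperature)
  lapply(protein_totals, function(P) {
    f <- function(L) {
      Lf <- solve_free_ligand(P, L, K, truth$coop_factor_c)
      100 * truth$q_max * adair_nu(Lf, K, truth$coop_factor_c) / truth$n_sites
    }
    saturation_exact(f, P, L_range)
  })
}
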