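#' Ground truth for the two-site cooperative binding simulator
#'
#' Defines the generative model behind all synthetic data: a protein with
#' two equivalent binding sites whose intrinsic per-site association
#' constant follows `K(T) = exp(-dH/(R T) + dS/R)`, with an intersite
#' cooperativity factor `c` (Adair formulation; `c = 1` is independent
#' sites, `c > 1` positive cooperativity). Static quenching ties the
#' tryptophan band intensity linearly to fractional occupancy,
#' `F = F0 (1 - q_max * theta)`, and the ligand's own absorbance produces
#' an inner-filter attenuation of the recorded signal.
#'
#' Defaults emulate a single-tryptophan ~40 kDa ATPase domain titrated
#' with a natural-product ligand: protein band at 330 nm (FWHM 30 nm),
#' ligand emission at 485 nm (FWHM 46 nm), binding enthalpy +130.13
#' kJ/mol, and an entropy chosen so that the Hill-equivalent constant
#' `K(288) * sqrt(c)` equals 2.67e5 M^-1, the observable scale of such a
#' system at 288 K (see the methods vignette for this calibration).
#'
#' @param delta_H binding enthalpy, J/mol.
#' @param delta_S binding entropy, J/(mol K); default anchors
#'   `K(288)*sqrt(c)` at 2.67e5 M^-1.
#' @param coop_factor_c intersite cooperativity factor (dimensionless).
#' @param n_sites number of sites (fixed at 2 in this generator).
#' @param q_max maximal fractional quench of the protein band, in (0, 1].
#' @param F0_ref unquenched reference intensity, arbitrary units.
#' @param protein_band,ligand_band c(center_nm, fwhm_nm) of the two
#'   emission bands.
#' @param ligand_emission_coeff ligand band amplitude per mol/L.
#' @param epsilon_ex,epsilon_em ligand extinction coefficients at the
#'   excitation/emission wavelengths, M^-1 cm^-1 (10 mm path basis).
#' @param tau_components data frame (alpha, tau ns) of the unquenched
#'   fluorophore decay.
#' @param cd_start,cd_end secondary-structure fractions (alpha, beta,
#'   turn, coil) at molar ratio 0 and at the end-state ratio 12.5.
#' @param noise_rel relative multiplicative intensity noise.
#' @param seed integer seed; all stochastic outputs are reproducible
#'   bit-for-bit given (seed, parameters).
#' @return Object of class `ground_truth`.
#' @export
ground_truth <- function(delta_H = 130.13e3,
                         delta_S = NULL,
                         coop_factor_c = 50,
                         n_sites = 2,
                         q_max = 0.8,
                         F0_ref = 1000,
                         protein_band = c(330, 30),
                         ligand_band = c(485, 46),
                         ligand_emission_coeff = 5e6,
                         epsilon_ex = 10000,
                         epsilon_em = 4000,
                         tau_components = data.frame(alpha = 1, tau = 2.2),
                         cd_start = c(alpha = 0.34, beta = 0.16, turn = 0.20, coil = 0.30),
                         cd_end = c(alpha = 0.26, beta = 0.31, turn = 0.22, coil = 0.21),
                         noise_rel = 0.01,
                         seed = 20201218) {
  if (is.null(delta_S))
    delta_S <- RGAS * (log(2.67e5 / sqrt(coop_factor_c)) + delta_H / (RGAS * 288))
  stopifnot(coop_factor_c >= 0, q_max > 0, q_max <= 1, n_sites == 2,
            noise_rel >= 0, F0_ref > 0)
  cd_start <- cd_start / sum(cd_start)
  cd_end <- cd_end / sum(cd_end)
  structure(list(
    delta_H = delta_H, delta_S = delta_S, coop_factor_c = coop_factor_c,
    n_sites = n_sites, q_max = q_max, F0_ref = F0_ref,
    protein_band = protein_band, ligand_band = ligand_band,
    ligand_emission_coeff = ligand_emission_coeff,
    epsilon_ex = epsilon_ex, epsilon_em = epsilon_em,
    tau_components = tau_components,
    cd_start = cd_start, cd_end = cd_end,
    noise_rel = noise_rel, seed = as.integer(seed)), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(paste0("<ground_truth> dH = %.4g kJ/mol, dS = %.4g J/(mol K), c = %g, ",
                     "K(288) = %.3g M^-1, noise = %g%%, seed = %d\n"),
              x$delta_H / 1000, x$delta_S, x$coop_factor_c,
              k_of_temperature(x$delta_H, x$delta_S, 288), x$noise_rel * 100,
              x$seed))
  invisible(x)
}

#' Intrinsic association constant at a temperature
#'
#' `K(T) = exp(-dH/(R T) + dS/R)` (the integrated van't Hoff relation).
#'
#' @param delta_H J/mol.
#' @param delta_S J/(mol K).
#' @param temperature K (vectorized).
#' @return K in M^-1.
#' @export
k_of_temperature <- function(delta_H, delta_S, temperature) {
  if (any(temperature <= 0)) stop_domain("temperature must be positive")
  exp(-delta_H / (RGAS * temperature) + delta_S / RGAS)
}

#' Adair binding density for two equivalent cooperative sites
#'
#' `nu = (2 K L + 2 c K^2 L^2) / (1 + 2 K L + c K^2 L^2)`, the exact
#' statistical-thermodynamic isotherm for two equivalent sites with
#' intrinsic constant `K` and cooperativity factor `c`. `nu` lies in
#' `[0, 2)`; with `c = 1` it reduces to the independent-sites form
#' `2 K L / (1 + K L)`.
#'
#' @param L_free free ligand concentration, mol/L (vectorized).
#' @param K intrinsic per-site constant, M^-1.
#' @param c cooperativity factor.
#' @return Sites occupied per protein.
#' @export
adair_nu <- function(L_free, K, c) {
  if (any(L_free < 0) || K < 0 || c < 0)
    stop_domain("L_free, K and c must be non-negative")
  KL <- K * L_free
  (2 * KL + 2 * c * KL^2) / (1 + 2 * KL + c * KL^2)
}

#' Solve the mass balance for free ligand
#'
#' Finds the unique `L_free` in `[0, L_tot]` with
#' `L_tot = L_free + nu(L_free) * P_tot` by bisection (the left side of
#' the residual is negative at 0 and non-negative at `L_tot`, and the
#' residual is strictly increasing). 100 bisection steps drive the
#' residual below `1e-12 * max(L_tot, 1e-12)`.
#'
#' @param P_tot total protein, mol/L.
#' @param L_tot total ligand, mol/L (vectorized).
#' @param K intrinsic per-site constant, M^-1.
#' @param c cooperativity factor.
#' @return Free ligand concentration(s), mol/L.
#' @export
solve_free_ligand <- function(P_tot, L_tot, K, c) {
  if (P_tot < 0 || any(L_tot < 0)) stop_domain("concentrations must be non-negative")
  vapply(L_tot, function(lt) {
    if (lt == 0 || K == 0) return(lt)
    f <- function(L) L + adair_nu(L, K, c) * P_tot - lt
    lo <- 0; hi <- lt
    for (i in 1:100) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }, 0)
}

# Gaussian band profile given center and FWHM.
band_profile <- function(wl, center, fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  exp(-(wl - center)^2 / (2 * sigma^2))
}

# Noiseless protein-band intensity and absorbances at one titration point.
forward_point <- function(truth, P_tot, L_tot, temperature) {
  K <- k_of_temperature(truth$delta_H, truth$delta_S, temperature)
  Lf <- solve_free_ligand(P_tot, L_tot, K, truth$coop_factor_c)
  nu <- adair_nu(Lf, K, truth$coop_factor_c)
  theta <- nu / truth$n_sites
  tail330 <- truth$ligand_emission_coeff * L_tot *
    band_profile(truth$protein_band[1], truth$ligand_band[1], truth$ligand_band[2])
  F330 <- truth$F0_ref * (1 - truth$q_max * theta) + tail330
  list(L_free = Lf, nu = nu, theta = theta, F330 = F330,
       A_ex = truth$epsilon_ex * L_tot, A_em = truth$epsilon_em * L_tot)
}

# Forward inner-filter attenuation (the inverse of correct_inner_filter).
apply_inner_filter <- function(F_true, A_ex, A_em) {
  F_true * 10^(-(5 * A_ex + A_em) / 10)
}

#' Simulate a ligand titration series
#'
#' For each total ligand concentration the mass balance is solved for free
#' ligand, occupancy sets the noiseless 330 nm intensity
#' `F = F0 (1 - q_max * theta)` (plus the far tail of the ligand's 485 nm
#' band), the ligand's absorbance attenuates the recorded signal by the
#' inner-filter factor, and multiplicative Gaussian noise (seed-pinned) is
#' applied. Mass balance holds exactly before noise.
#'
#' @param truth a [ground_truth].
#' @param protein_total mol/L.
#' @param temperature K.
#' @param ligand_grid mol/L; must start at 0 and increase strictly.
#' @param seed_offset integer mixed into the truth's seed so different
#'   series from one truth get independent noise streams.
#' @return A [titration_series] (with `F_corr` unset; apply
#'   [correct_series()]).
#' @export
simulate_titration <- function(truth, protein_total, temperature, ligand_grid,
                               seed_offset = 0) {
  if (ligand_grid[1] != 0 || any(diff(ligand_grid) <= 0))
    stop_domain("ligand_grid must start at 0 and increase strictly")
  fp <- forward_point(truth, protein_total, ligand_grid, temperature)
  F_att <- apply_inner_filter(fp$F330, fp$A_ex, fp$A_em)
  F_raw <- if (truth$noise_rel > 0) {
    with_seed(truth$seed + 7919 * seed_offset +
                round(protein_total * 1e9) + round(temperature), {
      F_att * (1 + rnorm(length(F_att), 0, truth$noise_rel))
    })
  } else F_att
  titration_series(protein_total, temperature,
                   data.frame(ligand_total = ligand_grid,
                              F_raw = pmax(F_raw, 0),
                              A_ex = fp$A_ex, A_em = fp$A_em))
}

#' Simulate an emission spectrum
#'
#' Two Gaussian bands: the protein band scaled by the quenched intensity
#' and the ligand band growing with total ligand.
#'
#' @param truth a [ground_truth].
#' @param protein_total,temperature,ligand_total condition.
#' @param wavelengths nm grid.
#' @return An [emission_spectrum] (noiseless).
#' @export
simulate_spectrum <- function(truth, protein_total, temperature, ligand_total,
                              wavelengths = seq(305, 570, by = 1)) {
  fp <- forward_point(truth, protein_total, ligand_total, temperature)
  prot <- (fp$F330 - truth$ligand_emission_coeff * ligand_total *
             band_profile(truth$protein_band[1], truth$ligand_band[1],
                          truth$ligand_band[2])) *
    band_profile(wavelengths, truth$protein_band[1], truth$protein_band[2])
  lig <- truth$ligand_emission_coeff * ligand_total *
    band_profile(wavelengths, truth$ligand_band[1], truth$ligand_band[2])
  emission_spectrum(wavelengths, pmax(prot + lig, 0), temperature,
                    protein_total, ligand_total)
}

#' Simulate a TCSPC decay trace
#'
#' Counts are Poisson draws around
#' `peak_counts * sum_i alpha_i exp(-t/tau_i)`. In the default (static
#' quenching) regime the lifetimes do not depend on ligand concentration;
#' `tau_scale` rescales every lifetime (set it to `F/F0` to construct a
#' collisional-quenching regime for classifier tests).
#'
#' @param truth a [ground_truth].
#' @param ligand_total mol/L (metadata; does not alter lifetimes).
#' @param n_channels number of time channels.
#' @param dt channel width, ns.
#' @param peak_counts expected counts in the first channel.
#' @param tau_scale lifetime scale factor (1 = static regime).
#' @param seed_offset integer mixed into the truth's seed.
#' @return A [decay_trace].
#' @export
simulate_decay <- function(truth, ligand_total = 0, n_channels = 256,
                           dt = 0.05, peak_counts = 1e4, tau_scale = 1,
                           seed_offset = 0) {
  if (n_channels < 50 || dt <= 0 || peak_counts <= 0)
    stop_domain("need n_channels >= 50, dt > 0, peak_counts > 0")
  t <- seq(0, by = dt, length.out = n_channels)
  comp <- truth$tau_components
  model <- rowSums(vapply(seq_len(nrow(comp)), function(i)
    comp$alpha[i] * exp(-t / (comp$tau[i] * tau_scale)),
    numeric(length(t))))
  lambda <- peak_counts * model / model[1]
  counts <- with_seed(truth$seed + 104729 * seed_offset +
                        round(ligand_total * 1e9) + 1, {
    rpois(length(lambda), lambda)
  })
  decay_trace(t, counts, ligand_total)
}

#' Simulate circular dichroism spectra along a titration
#'
#' Secondary-structure fractions interpolate linearly from the apo mix to
#' the end-state mix as the ligand:protein molar ratio goes from 0 to
#' 12.5. Each structure class contributes a fixed synthetic basis band
#' (Gaussian mixtures with the canonical alpha-helix double minimum at
#' 208/222 nm, the beta-sheet minimum near 218 nm, and disordered-coil
#' negative band near 198 nm); the mean-residue-ellipticity mixture is
#' converted back to millidegrees through the path length, concentration
#' and residue count.
#'
#' @param truth a [ground_truth].
#' @param molar_ratios numeric, ligand:protein molar ratios (>= 0).
#' @param protein_total mol/L.
#' @param path_length cm.
#' @param n_residues residue count.
#' @param wavelengths nm grid.
#' @return List of [cd_spectrum] objects, one per ratio.
#' @export
simulate_cd <- function(truth, molar_ratios, protein_total = 4e-6,
                        path_length = 0.01, n_residues = 383,
                        wavelengths = seq(200, 260, by = 0.5)) {
  if (any(molar_ratios < 0)) stop_domain("molar ratios must be non-negative")
  basis <- cd_basis(wavelengths)
  lapply(molar_ratios, function(r) {
    f <- cd_fractions(truth, r)
    stopifnot(abs(sum(f) - 1) < 1e-9)
    mre <- as.numeric(basis %*% f)
    theta <- mre * 10 * protein_total * path_length * n_residues
    cd_spectrum(wavelengths, theta, protein_total, path_length, n_residues,
                molar_ratio_label = sprintf("1:%g", r))
  })
}

# Linear interpolation of secondary-structure fractions with saturation
# at ratio 12.5.
cd_fractions <- function(truth, ratio) {
  a <- min(ratio / 12.5, 1)
  f <- (1 - a) * truth$cd_start + a * truth$cd_end
  f / sum(f)
}

# Synthetic mean-residue-ellipticity basis bands (deg cm^2/dmol), one
# column per structure class. Shapes are analytic stand-ins with the
# canonical band positions, not deconvolution library spectra.
cd_basis <- function(wl) {
  g <- function(center, fwhm) band_profile(wl, center, fwhm)
  alpha <- -33000 * (g(208, 12) + g(222, 14)) / 2 + 60000 * g(192, 10)
  beta <- -14000 * g(218, 20) + 25000 * g(196, 10)
  turn <- -4000 * g(225, 25) + 8000 * g(205, 15)
  coil <- -20000 * g(198, 14) + 2000 * g(220, 30)
  cbind(alpha = alpha, beta = beta, turn = turn, coil = coil)
}

#' Simulate a full study dataset
#'
#' Assembles the synthetic material a complete binding study uses:
#' titrations on a grid of protein concentrations and temperatures, decay
#' traces across the titration at one temperature, representative
#' emission spectra, and CD spectra along the molar-ratio series. The
#' generative truth is retained for recovery assertions.
#'
#' @param truth a [ground_truth].
#' @param protein_totals mol/L (default 4, 6, 8 uM).
#' @param temperatures K (default 288, 298, 308).
#' @param ligand_grid mol/L (default 0 to 20 uM in 0.5 uM steps).
#' @param decay_ligands mol/L at which decays are simulated.
#' @param cd_ratios molar ratios for CD.
#' @return Object of class `simulated_dataset` with elements `titrations`
#'   (list with `$series`, `$protein_total`, `$temperature`), `decays`,
#'   `spectra`, `cd`, `truth`.
#' @export
simulate_dataset <- function(truth,
                             protein_totals = c(4e-6, 6e-6, 8e-6),
                             temperatures = c(288, 298, 308),
                             ligand_grid = seq(0, 20e-6, by = 0.5e-6),
                             decay_ligands = seq(0, 20e-6, by = 5e-6),
                             cd_ratios = c(0, 2.5, 5, 7.5, 10, 12.5)) {
  grid <- expand.grid(P = protein_totals, T = temperatures)
  titrations <- lapply(seq_len(nrow(grid)), function(i) {
    simulate_titration(truth, grid$P[i], grid$T[i], ligand_grid,
                       seed_offset = i)
  })
  decays <- lapply(seq_along(decay_ligands), function(i)
    simulate_decay(truth, decay_ligands[i], seed_offset = i))
  spectra <- lapply(c(0, max(ligand_grid)), function(L)
    simulate_spectrum(truth, protein_totals[1], temperatures[1], L))
  cd <- simulate_cd(truth, cd_ratios, protein_total = protein_totals[1])
  structure(list(titrations = titrations, decays = decays, spectra = spectra,
                 cd = cd, truth = truth), class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("<simulated_dataset> %d titrations, %d decays, %d CD spectra\n",
              length(x$titrations), length(x$decays), length(x$cd)))
  invisible(x)
}
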