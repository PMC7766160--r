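#' Double-logarithm binding-constant fit
#'
#' Fits `log10((F0 - F)/F) = log10(K_a) + n * log10([L])` by ordinary least
#' squares over the titration points with measurable quenching. The slope
#' is the apparent binding stoichiometry `n` and the intercept gives the
#' apparent binding constant `K_a` of the 1:1 binding-equilibrium model.
#' Total ligand concentration stands in for free ligand, the standard
#' approximation of this plot. Points with `F >= F0` carry no binding
#' signal and are excluded with a warning.
#'
#' @param series a [titration_series].
#' @return Object of class `double_log_fit`: `K_a` (M^-1), `n_stoich`,
#'   `r_squared`, `stderr_logK`, `stderr_n`, `temperature`.
#' @export
fit_double_log <- function(series) {
  Fc <- series_intensities(series)
  L <- series$records$ligand_total
  F0 <- Fc[1]
  keep <- L > 0
  bad <- keep & Fc >= F0
  if (any(bad)) {
    warning(sprintf("excluding %d point(s) with F >= F0 (no quenching signal)",
                    sum(bad)), call. = FALSE)
    keep <- keep & !bad
  }
  if (sum(keep) < 3) stop_data("fewer than 3 usable double-log points")
  x <- log10(L[keep])
  y <- log10((F0 - Fc[keep]) / Fc[keep])
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))
  structure(list(
    K_a = 10^unname(coef(fit)[1]),
    n_stoich = unname(coef(fit)[2]),
    r_squared = sm$r.squared,
    stderr_logK = sm$coefficients[1, 2],
    stderr_n = sm$coefficients[2, 2],
    temperature = series$temperature,
    fit = fit), class = "double_log_fit")
}

#' @export
print.double_log_fit <- function(x, ...) {
  cat(sprintf("<double_log_fit> K_a = %.4g M^-1, n = %.3f (T = %.0f K, r^2 = %.4f)\n",
              x$K_a, x$n_stoich, x$temperature, x$r_squared))
  invisible(x)
}

#' van't Hoff decomposition
#'
#' Ordinary least squares of `ln K_a` versus `1/T`:
#' `ln K = -dH/(R T) + dS/R`, assuming temperature-independent dH and dS
#' over the fitted range. `dH = -slope * R`, `dS = intercept * R`, with
#' standard errors and the parameter covariance taken from the regression
#' (for exact error propagation into Gibbs energies).
#'
#' @param points a data frame (or list of pairs) with columns
#'   `temperature` (K) and `K_a` (M^-1); at least 2 distinct temperatures.
#' @return Object of class `thermo_params`: `delta_H`, `delta_S` (J units),
#'   `stderr_delta_H`, `stderr_delta_S`, `cov_HS`, `gas_constant`,
#'   `source_points`, `fit`.
#' @export
fit_vant_hoff <- function(points) {
  if (is.list(points) && !is.data.frame(points))
    points <- do.call(rbind, lapply(points, function(p)
      data.frame(temperature = p[[1]], K_a = p[[2]])))
  points <- as.data.frame(points)
  if (!all(c("temperature", "K_a") %in% names(points)))
    stop_domain("points need columns temperature, K_a")
  if (any(points$K_a <= 0)) stop_domain("all K_a must be positive")
  if (length(unique(points$temperature)) < 2)
    stop_data("need >= 2 distinct temperatures (rank-deficient design)")
  x <- 1 / points$temperature
  y <- log(points$K_a)
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))$coefficients
  V <- suppressWarnings(vcov(fit))
  exact <- nrow(points) == 2
  structure(list(
    delta_H = -unname(coef(fit)[2]) * RGAS,
    delta_S = unname(coef(fit)[1]) * RGAS,
    stderr_delta_H = if (exact) NA_real_ else sm[2, 2] * RGAS,
    stderr_delta_S = if (exact) NA_real_ else sm[1, 2] * RGAS,
    cov_HS = if (exact) NA_real_ else -V[1, 2] * RGAS^2,
    gas_constant = RGAS,
    source_points = points[, c("temperature", "K_a")],
    fit = fit), class = "thermo_params")
}

#' @export
print.thermo_params <- function(x, ...) {
  cat(sprintf("<thermo_params> dH = %.4g kJ/mol, dS = %.4g J/(mol K) [%d temperatures]\n",
              x$delta_H / 1000, x$delta_S, nrow(x$source_points)))
  invisible(x)
}

#' Gibbs free energy of binding
#'
#' `dG(T) = dH - T dS`, with the uncertainty propagated from the van't
#' Hoff regression including the (strongly negative) slope-intercept
#' covariance.
#'
#' @param params a [fit_vant_hoff()] result.
#' @param temperature K (vectorized).
#' @return Data frame with columns `temperature`, `delta_G` (J/mol),
#'   `stderr_delta_G`.
#' @export
gibbs_energy <- function(params, temperature) {
  if (any(temperature <= 0)) stop_domain("temperature must be positive")
  dG <- params$delta_H - temperature * params$delta_S
  se <- if (is.finite(params$stderr_delta_H)) {
    sqrt(params$stderr_delta_H^2 + temperature^2 * params$stderr_delta_S^2 -
           2 * temperature * params$cov_HS)
  } else rep(NA_real_, length(temperature))
  data.frame(temperature = temperature, delta_G = dG, stderr_delta_G = se)
}

#' Reconstruct K(T) from fitted thermodynamic parameters
#'
#' `K(T) = exp(-dH/(R T) + dS/R)`; on the fitted parameters this
#' reproduces the van't Hoff regression line exactly.
#'
#' @param params a [fit_vant_hoff()] result (or any list with `delta_H`,
#'   `delta_S`).
#' @param temperature K (vectorized).
#' @return K in M^-1.
#' @export
k_of_temperature_params <- function(params, temperature) {
  k_of_temperature(params$delta_H, params$delta_S, temperature)
}

#' Classify the thermodynamic driving forces
#'
#' Ross-Subramanian sign convention: both dH and dS positive indicates
#' predominantly non-specific (hydrophobic) contacts; both negative, van
#' der Waals and hydrogen bonding; dH negative with dS positive,
#' electrostatic interactions. Boundary zeros resolve toward the dS sign.
#'
#' @param delta_H J/mol.
#' @param delta_S J/(mol K).
#' @return One of `"nonspecific_hydrophobic"`, `"vdw_hbond"`,
#'   `"electrostatic"`.
#' @export
classify_driving_forces <- function(delta_H, delta_S) {
  if (delta_S >= 0) {
    if (delta_H > 0) "nonspecific_hydrophobic" else "electrostatic"
  } else {
    "vdw_hbond"
  }
}
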