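#' Stern-Volmer fit
#'
#' Ordinary least squares of `F0/F` against total quencher concentration,
#' `F0/F = 1 + K_SV * [Q]`, using inner-filter-corrected intensities. The
#' slope is the Stern-Volmer constant; the intercept is reported as a
#' diagnostic (it should be close to 1 for a single fluorophore class).
#'
#' @param series a [titration_series]; needs at least 3 titration points
#'   beyond the zero-ligand reference.
#' @return Object of class `stern_volmer_fit` with elements `K_SV` (M^-1),
#'   `intercept`, `r_squared`, `stderr_K_SV`, `temperature`.
#' @export
fit_stern_volmer <- function(series) {
  Fc <- series_intensities(series)
  L <- series$records$ligand_total
  if (any(Fc <= 0)) stop_domain("all corrected intensities must be positive")
  F0 <- Fc[1]
  if (length(L) < 4) stop_data("need >= 3 titration points beyond the zero-ligand reference")
  ratio <- F0 / Fc
  fit <- lm(ratio ~ L)
  sm <- suppressWarnings(summary(fit))
  structure(list(
    K_SV = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = sm$r.squared,
    stderr_K_SV = sm$coefficients[2, 2],
    temperature = series$temperature,
    fit = fit), class = "stern_volmer_fit")
}

#' @export
print.stern_volmer_fit <- function(x, ...) {
  cat(sprintf("<stern_volmer_fit> K_SV = %.4g +/- %.2g M^-1 (T = %.0f K, r^2 = %.4f)\n",
              x$K_SV, x$stderr_K_SV, x$temperature, x$r_squared))
  invisible(x)
}

#' Bimolecular quenching constant
#'
#' `k_q = K_SV / tau0`. Values far above the diffusion-controlled limit
#' (~1e10 M^-1 s^-1) indicate static quenching (ground-state complex
#' formation) rather than collisional deactivation.
#'
#' @param K_SV Stern-Volmer constant, M^-1.
#' @param tau0 unquenched fluorophore lifetime, seconds.
#' @return k_q in M^-1 s^-1.
#' @export
bimolecular_constant <- function(K_SV, tau0) {
  if (any(tau0 <= 0)) stop_domain("tau0 must be positive")
  K_SV / tau0
}

#' Classify the quenching mechanism
#'
#' Combines three lines of evidence the way a fluorescence study does:
#' (i) whether the fluorophore lifetime stays constant under titration
#' (`tau0/tau ~ 1`, the static signature) or tracks `F0/F` (the dynamic
#' signature); (ii) whether the bimolecular constants `k_q = K_SV/tau0`
#' exceed the diffusion limit; (iii) the temperature trend of `K_SV`,
#' reported but not decisive when (i) and (ii) agree.
#'
#' The decision table is total:
#' * static: lifetime flat within `lifetime_tolerance` AND all
#'   `k_q > k_q_threshold`;
#' * dynamic: `tau0/tau` tracks `F0/F` within `lifetime_tolerance` AND all
#'   `k_q <= k_q_threshold`;
#' * ambiguous: anything else (including missing lifetime data, flagged
#'   with a reason).
#'
#' @param sv_fits list of [fit_stern_volmer()] results at distinct
#'   temperatures (at least 2 for a trend).
#' @param decay_fits list of [fit_decay()] results across the titration,
#'   each carrying `ligand_total`; at least 2 (one must be the zero-ligand
#'   reference).
#' @param tau0 unquenched average lifetime, ns (conventionally the
#'   zero-ligand decay fit's `tau_avg`).
#' @param k_q_threshold diffusion limit for `k_q`, M^-1 s^-1.
#' @param lifetime_tolerance tolerance on `|tau0/tau - 1|` (and on the
#'   match between `tau0/tau` and `F0/F`).
#' @param sv_reference temperature (K) whose `K_SV` is used to predict
#'   `F0/F` at the lifetime measurements' ligand concentrations; defaults
#'   to the fitted temperature closest to 298 K.
#' @return Object of class `quenching_assessment` with elements
#'   `mechanism`, `ksv_temperature_trend`, `max_lifetime_ratio_deviation`,
#'   `k_q_values`, `reason`.
#' @export
classify_mechanism <- function(sv_fits, decay_fits, tau0,
                               k_q_threshold = 1e10,
                               lifetime_tolerance = 0.05,
                               sv_reference = NULL) {
  if (length(sv_fits) < 1) stop_data("need at least one Stern-Volmer fit")
  temps <- vapply(sv_fits, function(f) f$temperature, 0)
  ksv <- vapply(sv_fits, function(f) f$K_SV, 0)
  k_q <- bimolecular_constant(ksv, tau0 * 1e-9)
  names(k_q) <- as.character(temps)

  # K_SV temperature trend: slope sign tested against 2 x stderr
  trend <- "flat"
  if (length(temps) >= 2) {
    tf <- lm(ksv ~ temps)
    sl <- suppressWarnings(summary(tf))$coefficients
    if (nrow(sl) == 2 && is.finite(sl[2, 2]) && sl[2, 2] > 0) {
      if (sl[2, 1] > 2 * sl[2, 2]) trend <- "increasing"
      else if (sl[2, 1] < -2 * sl[2, 2]) trend <- "decreasing"
    } else if (length(temps) == 2) {
      trend <- if (diff(ksv[order(temps)]) > 0) "increasing" else "decreasing"
    }
  }

  if (length(decay_fits) < 2) {
    return(structure(list(
      mechanism = "ambiguous", ksv_temperature_trend = trend,
      max_lifetime_ratio_deviation = NA_real_, k_q_values = k_q,
      reason = "missing lifetime data: fewer than 2 decay fits"),
      class = "quenching_assessment"))
  }

  tau <- vapply(decay_fits, function(f) f$tau_avg, 0)
  Ld <- vapply(decay_fits, function(f) f$ligand_total %||% NA_real_, 0)
  ratio <- tau0 / tau
  max_dev <- max(abs(ratio - 1))

  # predicted F0/F at the lifetime measurements' ligand concentrations
  ref_T <- sv_reference %||% temps[which.min(abs(temps - 298))]
  K_ref <- ksv[which.min(abs(temps - ref_T))]
  tracks <- FALSE
  if (all(is.finite(Ld))) {
    f0f <- 1 + K_ref * Ld
    tracks <- all(abs(ratio / f0f - 1) <= lifetime_tolerance)
  }

  kq_high <- all(k_q > k_q_threshold)
  kq_low <- all(k_q <= k_q_threshold)
  lifetime_flat <- max_dev < lifetime_tolerance

  if (lifetime_flat && kq_high) {
    mech <- "static"; reason <- "lifetime invariant and k_q above diffusion limit"
  } else if (tracks && kq_low) {
    mech <- "dynamic"; reason <- "tau0/tau tracks F0/F and k_q below diffusion limit"
  } else {
    mech <- "ambiguous"; reason <- "conflicting lifetime and k_q evidence"
  }
  structure(list(
    mechanism = mech, ksv_temperature_trend = trend,
    max_lifetime_ratio_deviation = max_dev, k_q_values = k_q,
    reason = reason), class = "quenching_assessment")
}

#' @export
print.quenching_assessment <- function(x, ...) {
  cat(sprintf("<quenching_assessment> mechanism: %s (K_SV trend %s)\n  %s\n",
              x$mechanism, x$ksv_temperature_trend, x$reason))
  invisible(x)
}
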