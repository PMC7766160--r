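#' Fit a saturation (quench-percentage) curve
#'
#' Fits `deltaF` versus `log10(ligand_total)` with an asymmetric
#' (5-parameter Richards) logistic,
#' `deltaF(x) = floor + (ceiling - floor) / (1 + 10^(s (mid - x)))^g`.
#' With `asymmetry` fixed at 1 this is the symmetric 4-parameter logistic;
#' the extra shape parameter is needed because titrations that approach
#' the stoichiometric regime produce visibly skewed sigmoids, and an
#' unbiased fitted curve is what makes the curve invertible for
#' binding-density work.
#'
#' Points are weighted by `1/(1 - deltaF/100)^2`: for multiplicative
#' intensity noise the variance of the quench percentage shrinks as the
#' signal is quenched.
#'
#' @param deltaF_points data frame with columns `ligand_total` (mol/L) and
#'   `deltaF` (percent); at least 6 points with `ligand_total > 0`.
#' @param protein_total mol/L, carried for binding-density analysis.
#' @param asymmetry `NULL` to fit the asymmetry (default), or a fixed
#'   positive value (1 = symmetric logistic).
#' @param range_trim percent trimmed from each end of the fitted span to
#'   define the invertible range (default 2).
#' @return Object of class `saturation_curve`: `params` (floor, ceiling,
#'   log10_midpoint, steepness, asymmetry), `valid_deltaF_range`,
#'   `r_squared`, `protein_total`, `fit`, `data`.
#' @export
fit_saturation <- function(deltaF_points, protein_total, asymmetry = NULL,
                           range_trim = 2) {
  d <- as.data.frame(deltaF_points)
  if (!all(c("ligand_total", "deltaF") %in% names(d)))
    stop_domain("deltaF_points needs columns ligand_total, deltaF")
  d <- d[d$ligand_total > 0, ]
  if (nrow(d) < 6) stop_data("need >= 6 points with ligand_total > 0")
  # monotonicity within noise: strongly decreasing runs flag bad data
  rough_sd <- sd(diff(d$deltaF))
  if (any(diff(d$deltaF) < -6 * max(rough_sd, 1)))
    stop_data("deltaF is non-monotone beyond tolerance")
  x <- log10(d$ligand_total)
  y <- d$deltaF
  w <- 1 / pmax(1 - y / 100, 0.05)^2
  st <- list(fl = max(min(y), 0), ce = max(y),
             mid = x[which.min(abs(y - (min(y) + max(y)) / 2))], s = 1)
  lower <- c(-50, 1, min(x) - 3, 0.05)
  upper <- c(50, 200, max(x) + 3, 20)
  if (is.null(asymmetry)) {
    st$g <- 1
    lower <- c(lower, 0.02); upper <- c(upper, 50)
    form <- y ~ fl + (ce - fl) / (1 + 10^(s * (mid - x)))^g
  } else {
    if (asymmetry <= 0) stop_domain("asymmetry must be positive")
    form <- y ~ fl + (ce - fl) / (1 + 10^(s * (mid - x)))^asym_fixed
  }
  env <- data.frame(x = x, y = y)
  if (!is.null(asymmetry)) env$asym_fixed <- asymmetry
  fit <- tryCatch(
    nlsLM(form, data = env, start = st, weights = w,
          lower = lower, upper = upper,
          control = nls.lm.control(maxiter = 1000)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # second deterministic start: steeper, skewed
    st2 <- st; st2$s <- 2; st2$mid <- st$mid - 0.2
    if (is.null(asymmetry)) st2$g <- 0.5
    fit <- tryCatch(
      nlsLM(form, data = env, start = st2, weights = w,
            lower = lower, upper = upper,
            control = nls.lm.control(maxiter = 1000)),
      error = function(e) NULL)
  }
  if (is.null(fit)) stop_fit("saturation curve fit did not converge")
  p <- coef(fit)
  params <- c(floor = unname(p[["fl"]]), ceiling = unname(p[["ce"]]),
              log10_midpoint = unname(p[["mid"]]), steepness = unname(p[["s"]]),
              asymmetry = if (is.null(asymmetry)) unname(p[["g"]]) else asymmetry)
  ss_res <- sum(w * resid(fit)^2)
  ss_tot <- sum(w * (y - sum(w * y) / sum(w))^2)
  structure(list(
    params = params,
    valid_deltaF_range = c(params[["floor"]] + range_trim,
                           min(params[["ceiling"]], max(y)) - range_trim),
    r_squared = 1 - ss_res / ss_tot,
    protein_total = protein_total,
    fit = fit,
    data = d), class = "saturation_curve")
}

#' Exact saturation curve from a known quench function
#'
#' Wraps an analytic `deltaF(ligand_total)` relation (for example the
#' simulator's own noiseless forward model) in the `saturation_curve`
#' interface, with inversion by bisection to near machine precision. Used
#' to study the binding-density extraction in isolation from sigmoid
#' fitting error.
#'
#' @param deltaF_fun monotone increasing function of ligand_total (mol/L)
#'   returning deltaF in percent.
#' @param protein_total mol/L.
#' @param ligand_range c(min, max) mol/L over which the curve is defined
#'   (min > 0).
#' @param range_trim percent trimmed from each end of the span.
#' @return A `saturation_curve` (subclass `saturation_curve_exact`).
#' @export
saturation_exact <- function(deltaF_fun, protein_total, ligand_range,
                             range_trim = 2) {
  if (ligand_range[1] <= 0) stop_domain("ligand_range must be positive")
  lo_f <- deltaF_fun(ligand_range[1])
  hi_f <- deltaF_fun(ligand_range[2])
  structure(list(
    params = NULL,
    deltaF_fun = deltaF_fun,
    ligand_range = ligand_range,
    valid_deltaF_range = c(lo_f + range_trim, hi_f - range_trim),
    r_squared = 1,
    protein_total = protein_total,
    data = NULL), class = c("saturation_curve_exact", "saturation_curve"))
}

#' Evaluate a saturation curve
#'
#' @param object a `saturation_curve`.
#' @param ligand_total mol/L (vectorized).
#' @param ... unused.
#' @return deltaF in percent.
#' @export
predict.saturation_curve <- function(object, ligand_total, ...) {
  if (inherits(object, "saturation_curve_exact"))
    return(object$deltaF_fun(ligand_total))
  p <- object$params
  p[["floor"]] + (p[["ceiling"]] - p[["floor"]]) /
    (1 + 10^(p[["steepness"]] * (p[["log10_midpoint"]] - log10(ligand_total))))^p[["asymmetry"]]
}

#' Invert a saturation curve
#'
#' Returns the unique total ligand concentration at which the curve takes
#' the requested quench percentage. For the fitted logistic the inverse is
#' closed-form; exact curves are inverted by bisection. The round trip
#' `predict(curve, invert_saturation(curve, dF)) == dF` holds to numerical
#' precision.
#'
#' @param curve a `saturation_curve`.
#' @param deltaF percent, inside `curve$valid_deltaF_range`.
#' @return ligand_total in mol/L (vectorized over `deltaF`).
#' @export
invert_saturation <- function(curve, deltaF) {
  rng <- curve$valid_deltaF_range
  if (any(deltaF < rng[1] - 1e-9) || any(deltaF > rng[2] + 1e-9))
    stop_range(sprintf("deltaF outside invertible range [%.2f, %.2f]",
                       rng[1], rng[2]))
  if (inherits(curve, "saturation_curve_exact")) {
    return(vapply(deltaF, function(dd) {
      uniroot(function(L) curve$deltaF_fun(L) - dd,
              interval = curve$ligand_range, tol = 1e-15)$root
    }, 0))
  }
  p <- curve$params
  frac <- ((p[["ceiling"]] - p[["floor"]]) / (deltaF - p[["floor"]]))^(1 / p[["asymmetry"]]) - 1
  10^(p[["log10_midpoint"]] - log10(frac) / p[["steepness"]])
}

# Delta-method standard error of the inverted concentration, from the
# sigmoid fit's parameter covariance. Exact curves have zero error.
invert_saturation_se <- function(curve, deltaF) {
  L0 <- invert_saturation(curve, deltaF)
  if (inherits(curve, "saturation_curve_exact") || is.null(curve$fit))
    return(cbind(L = L0, se = 0))
  V <- suppressWarnings(vcov(curve$fit))
  pn <- colnames(V)
  p <- coef(curve$fit)
  se <- vapply(seq_along(deltaF), function(i) {
    gr <- vapply(pn, function(nm) {
      ph <- p
      h <- max(abs(p[[nm]]) * 1e-5, 1e-8)
      ph[[nm]] <- p[[nm]] + h
      cv <- curve
      cv$params <- translate_params(ph, curve$params)
      (invert_saturation(cv, deltaF[i]) - L0[i]) / h
    }, 0)
    val <- t(gr) %*% V %*% gr
    sqrt(max(val, 0))
  }, 0)
  cbind(L = L0, se = se)
}

translate_params <- function(p, template) {
  out <- template
  map <- c(fl = "floor", ce = "ceiling", mid = "log10_midpoint",
           s = "steepness", g = "asymmetry")
  for (nm in names(p)) if (nm %in% names(map)) out[[map[[nm]]]] <- p[[nm]]
  out
}

#' @export
print.saturation_curve <- function(x, ...) {
  if (inherits(x, "saturation_curve_exact")) {
    cat(sprintf("<saturation_curve> exact, P = %.3g M, range dF = [%.1f, %.1f]%%\n",
                x$protein_total, x$valid_deltaF_range[1], x$valid_deltaF_range[2]))
  } else {
    p <- x$params
    cat(sprintf("<saturation_curve> P = %.3g M, mid = 10^%.2f M, span %.1f-%.1f%%, r^2 = %.4f\n",
                x$protein_total, p[["log10_midpoint"]], p[["floor"]],
                p[["ceiling"]], x$r_squared))
  }
  invisible(x)
}
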