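#' Binding-density extraction (interaction density function)
#'
#' The model-free step at the heart of the binding-density method: if two
#' or more titrations at different total protein concentrations show the
#' same fractional signal change, they share the same average binding
#' density `nu` and free ligand concentration. Mass conservation,
#' `ligand_total = L_free + nu * protein_total`, then makes the plot of
#' `ligand_total` against `protein_total` at a fixed quench percentage a
#' straight line with slope `nu` and intercept `L_free`.
#'
#' For each level of a quench-percentage grid the saturation curves are
#' inverted, and a weighted least-squares line across protein
#' concentrations yields one `(nu, L_free)` pair. Weights are the inverse
#' variances of the inverted concentrations (delta method on the sigmoid
#' fits). Slightly negative intercepts (within 2 standard errors) are
#' clamped to zero with a warning; larger violations are retained but
#' flagged.
#'
#' @param curves list of >= 2 [fit_saturation()]/[saturation_exact()]
#'   curves at distinct protein concentrations (3 or more recommended).
#' @param deltaF_grid percent levels at which to extract binding
#'   densities; default 15 levels evenly spanning the intersection of the
#'   curves' invertible ranges.
#' @param n_levels grid size when `deltaF_grid` is NULL.
#' @return Data frame of class `binding_density` with columns `deltaF`,
#'   `nu_total`, `L_free`, `stderr_nu`, `stderr_Lfree`, `r_squared`,
#'   `flagged`.
#' @export
binding_density <- function(curves, deltaF_grid = NULL, n_levels = 15) {
  if (length(curves) < 2)
    stop_data("need >= 2 saturation curves at distinct protein concentrations")
  P <- vapply(curves, function(cv) cv$protein_total, 0)
  if (anyDuplicated(P))
    stop_domain("protein concentrations must be distinct")
  lo <- max(vapply(curves, function(cv) cv$valid_deltaF_range[1], 0))
  hi <- min(vapply(curves, function(cv) cv$valid_deltaF_range[2], 0))
  if (hi <= lo)
    stop_range("saturation curves have no common invertible deltaF range")
  if (is.null(deltaF_grid)) deltaF_grid <- seq(lo, hi, length.out = n_levels)
  if (any(deltaF_grid < lo - 1e-9 | deltaF_grid > hi + 1e-9))
    stop_range("deltaF_grid extends outside the common invertible range")

  rows <- lapply(deltaF_grid, function(g) {
    iv <- vapply(curves, function(cv) invert_saturation_se(cv, g)[1, ], c(L = 0, se = 0))
    L <- iv["L", ]
    se <- iv["se", ]
    w <- if (all(se > 0)) 1 / se^2 else rep(1, length(L))
    fit <- lm(L ~ P, weights = w)
    cf <- suppressWarnings(summary(fit))$coefficients
    # guard against rank issues with 2 curves (exact line: zero residual)
    se_int <- if (nrow(cf) == 2 && is.finite(cf[1, 2])) cf[1, 2] else 0
    se_slp <- if (nrow(cf) == 2 && is.finite(cf[2, 2])) cf[2, 2] else 0
    r2 <- suppressWarnings(summary(fit))$r.squared
    data.frame(deltaF = g, nu_total = unname(coef(fit)[2]),
               L_free = unname(coef(fit)[1]),
               stderr_nu = se_slp, stderr_Lfree = se_int,
               r_squared = r2, flagged = FALSE)
  })
  out <- do.call(rbind, rows)
  neg <- out$L_free < 0
  mild <- neg & out$L_free >= -2 * out$stderr_Lfree
  if (any(mild)) {
    warning(sprintf("clamping %d slightly negative L_free intercept(s) to 0",
                    sum(mild)), call. = FALSE)
    out$L_free[mild] <- 0
  }
  if (any(neg & !mild)) {
    warning(sprintf("%d level(s) have L_free < -2 stderr: flagged, check data quality",
                    sum(neg & !mild)), call. = FALSE)
    out$flagged[neg & !mild] <- TRUE
  }
  class(out) <- c("binding_density", "data.frame")
  out
}

#' Scatchard diagnostic
#'
#' Builds the Scatchard plot `(x = nu, y = nu/L_free)` from binding-density
#' points and fits a quadratic `y = a + b x + c x^2`. Concavity significant
#' at 2 standard errors classifies the cooperativity: negative concavity
#' (a humped profile) means positive cooperativity, positive concavity
#' negative cooperativity, otherwise the plot is consistent with
#' identical independent sites (a straight line).
#'
#' @param points a [binding_density()] result (>= 5 usable points with
#'   `L_free > 0`).
#' @return Object of class `scatchard_diagnostic`: `points` (x, y),
#'   `quadratic_coefficient` (M^-1 per site^2), `quadratic_stderr`,
#'   `classification`.
#' @export
scatchard <- function(points) {
  d <- as.data.frame(points)
  drop <- d$L_free <= 0
  if (any(drop)) {
    warning(sprintf("excluding %d point(s) with L_free <= 0 from Scatchard plot",
                    sum(drop)), call. = FALSE)
    d <- d[!drop, ]
  }
  if (nrow(d) < 5) stop_data("need >= 5 points with positive L_free")
  x <- d$nu_total
  y <- d$nu_total / d$L_free
  fit <- lm(y ~ x + I(x^2))
  cf <- suppressWarnings(summary(fit))$coefficients
  cc <- cf["I(x^2)", 1]
  se <- cf["I(x^2)", 2]
  classification <-
    if (is.finite(se) && cc < -2 * se) "positive_cooperativity"
    else if (is.finite(se) && cc > 2 * se) "negative_cooperativity"
    else "noncooperative"
  structure(list(points = data.frame(x = x, y = y),
                 quadratic_coefficient = cc, quadratic_stderr = se,
                 classification = classification, fit = fit),
            class = "scatchard_diagnostic")
}

#' @export
print.scatchard_diagnostic <- function(x, ...) {
  cat(sprintf("<scatchard_diagnostic> %s (c = %.3g +/- %.2g)\n",
              x$classification, x$quadratic_coefficient, x$quadratic_stderr))
  invisible(x)
}

#' Hill fit of binding-density points
#'
#' Weighted nonlinear least squares of the Hill isotherm
#' `nu = n (K_b L)^h / (1 + (K_b L)^h)` to `(L_free, nu)` binding-density
#' points: `n` is the number of (equivalent) sites, `K_b` the binding
#' constant and `h` the Hill coefficient. Weights start at
#' `1/stderr_nu^2` and are refined by two effective-variance iterations
#' that fold the `L_free` abscissa errors into the residual variance;
#' several deterministic starting points are tried and the best weighted
#' fit kept. Levels with unresolved `L_free` (below `lfree_min_sigma`
#' standard errors) or flagged by [binding_density()] are excluded.
#'
#' @param points a [binding_density()] result (or any data frame with
#'   `nu_total`, `L_free`, optionally `stderr_nu`, `stderr_Lfree`).
#' @param constrain_h_le_n refit with `h <= n` enforced (reported
#'   separately by the pipeline; default FALSE).
#' @param lfree_min_sigma resolution filter on `L_free` (default 2).
#' @return Object of class `hill_fit`: `n_sites`, `K_b` (M^-1), `h`,
#'   `covariance` (3x3), `r_squared`.
#' @export
fit_hill <- function(points, constrain_h_le_n = FALSE, lfree_min_sigma = 2) {
  d <- as.data.frame(points)
  if (!"stderr_nu" %in% names(d)) d$stderr_nu <- 0
  if (!"stderr_Lfree" %in% names(d)) d$stderr_Lfree <- 0
  if (!"flagged" %in% names(d)) d$flagged <- FALSE
  usable <- d$nu_total > 0 & d$L_free > 0 & !d$flagged &
    d$L_free > lfree_min_sigma * d$stderr_Lfree
  d <- d[usable, ]
  if (nrow(d) < 5) stop_data("need >= 5 usable binding-density points")
  if (min(d$nu_total) > 0.25 * max(d$nu_total))
    warning("binding-density points poorly span the low-saturation region",
            call. = FALSE)
  Lf <- d$L_free; nu <- d$nu_total
  base_var <- pmax(d$stderr_nu^2, (0.01 * max(nu))^2)
  K0 <- 1 / Lf[which.min(abs(nu - max(nu) / 2))]
  starts <- list(
    list(n = min(ceiling(max(nu)), 8), K_b = K0, h = 1),
    list(n = 2, K_b = K0, h = 2),
    list(n = min(max(nu) * 1.2, 8), K_b = 1 / median(Lf), h = 1.5))
  h_upper <- if (constrain_h_le_n) NA else 12
  best <- NULL; best_ssr <- Inf
  init_w <- function(st) {
    dnu <- with(st, {K_b <- if (!is.null(st$K_b)) st$K_b else exp(st$lK)
      n * h * (K_b * Lf)^h / (Lf * (1 + (K_b * Lf)^h)^2)})
    1 / pmax(base_var + (dnu * d$stderr_Lfree)^2, 1e-12)
  }
  for (st in starts) {
    w <- init_w(st)
    fit <- NULL
    for (it in 1:3) {
      up <- c(8, 1e12, if (constrain_h_le_n) max(st$n, 0.3) else h_upper)
      fit <- tryCatch(
        nlsLM(nu ~ n * (K_b * Lf)^h / (1 + (K_b * Lf)^h),
              data = data.frame(nu = nu, Lf = Lf),
              start = st, weights = w,
              lower = c(0.2, 1, 0.05), upper = up,
              control = nls.lm.control(maxiter = 1000)),
        error = function(e) NULL)
      if (is.null(fit)) break
      st <- as.list(coef(fit))
      dnu <- with(st, n * h * (K_b * Lf)^h / (Lf * (1 + (K_b * Lf)^h)^2))
      w <- 1 / pmax(base_var + (dnu * d$stderr_Lfree)^2, 1e-12)
    }
    if (!is.null(fit)) {
      ssr <- sum(w * resid(fit)^2)
      if (ssr < best_ssr) { best_ssr <- ssr; best <- fit; best_w <- w }
    }
  }
  if (is.null(best)) stop_fit("Hill fit did not converge from any start")
  p <- coef(best)
  ss_tot <- sum(best_w * (nu - sum(best_w * nu) / sum(best_w))^2)
  structure(list(
    n_sites = unname(p[["n"]]), K_b = unname(p[["K_b"]]), h = unname(p[["h"]]),
    covariance = tryCatch(vcov(best), error = function(e) matrix(NA, 3, 3)),
    r_squared = 1 - best_ssr / ss_tot,
    n_points = nrow(d),
    fit = best), class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> n = %.2f sites, K_b = %.4g M^-1, h = %.2f (%d points, r^2 = %.4f)\n",
              x$n_sites, x$K_b, x$h, x$n_points, x$r_squared))
  invisible(x)
}

#' Hill fit with the site count shared across datasets
#'
#' The number of binding sites is a structural property and does not
#' change with temperature, so a recovery study with binding-density
#' points at several temperatures can fit one shared `n` together with a
#' per-dataset `K_b` and `h`. Datasets that reach saturation pin `n`,
#' stabilizing `K_b` in datasets that do not.
#'
#' @param points_list list of [binding_density()] results (one per
#'   dataset/temperature).
#' @param lfree_min_sigma resolution filter on `L_free` (default 2).
#' @return List with `n_sites`, and data frame `per_dataset` with columns
#'   `K_b`, `h` in the order of `points_list`.
#' @export
fit_hill_global <- function(points_list, lfree_min_sigma = 2) {
  m <- length(points_list)
  if (m < 1) stop_data("empty points list")
  dl <- lapply(seq_len(m), function(i) {
    d <- as.data.frame(points_list[[i]])
    if (!"stderr_nu" %in% names(d)) d$stderr_nu <- 0
    if (!"stderr_Lfree" %in% names(d)) d$stderr_Lfree <- 0
    if (!"flagged" %in% names(d)) d$flagged <- FALSE
    ok <- d$nu_total > 0 & d$L_free > 0 & !d$flagged
    strict <- ok & d$L_free > lfree_min_sigma * d$stderr_Lfree
    # a dataset whose free-ligand levels are all unresolved still carries
    # saturation information; keep it with its (large) errors
    d <- if (sum(strict) >= 3) d[strict, ] else d[ok, ]
    if (nrow(d)) d$dataset <- i
    d
  })
  d <- do.call(rbind, dl)
  if (nrow(d) < 5 * m) warning("few usable points per dataset", call. = FALSE)
  lK0 <- vapply(dl, function(x)
    log(1 / x$L_free[which.min(abs(x$nu_total - max(x$nu_total) / 2))]), 0)
  model <- function(dataset, Lf, n, lK, h) {
    n * (exp(lK[dataset]) * Lf)^h[dataset] /
      (1 + (exp(lK[dataset]) * Lf)^h[dataset])
  }
  par0 <- c(n = 2, lK0, rep(1.5, m))
  base_var <- pmax(d$stderr_nu^2, (0.01 * max(d$nu_total))^2)
  dnu0 <- {
    K0 <- exp(lK0)[d$dataset]
    2 * 1.5 * (K0 * d$L_free)^1.5 / (d$L_free * (1 + (K0 * d$L_free)^1.5)^2)
  }
  w <- 1 / pmax(base_var + (dnu0 * d$stderr_Lfree)^2, 1e-12)
  fn <- function(par) {
    n <- par[1]; lK <- par[2:(m + 1)]; h <- par[(m + 2):(2 * m + 1)]
    sqrt(w) * (d$nu_total - model(d$dataset, d$L_free, n, lK, h))
  }
  lower <- c(0.2, rep(log(1), m), rep(0.05, m))
  upper <- c(8, rep(log(1e12), m), rep(12, m))
  res <- NULL
  for (it in 1:3) {
    res <- minpack.lm::nls.lm(par = par0, fn = fn, lower = lower, upper = upper,
                              control = nls.lm.control(maxiter = 1000))
    par0 <- res$par
    n <- par0[1]; lK <- par0[2:(m + 1)]; h <- par0[(m + 2):(2 * m + 1)]
    dnu <- n * h[d$dataset] * (exp(lK[d$dataset]) * d$L_free)^h[d$dataset] /
      (d$L_free * (1 + (exp(lK[d$dataset]) * d$L_free)^h[d$dataset])^2)
    w <- 1 / pmax(base_var + (dnu * d$stderr_Lfree)^2, 1e-12)
  }
  par <- res$par
  list(n_sites = unname(par[1]),
       per_dataset = data.frame(K_b = exp(unname(par[2:(m + 1)])),
                                h = unname(par[(m + 2):(2 * m + 1)])))
}

#' Classify cooperativity from a Hill coefficient
#'
#' @param h Hill coefficient (> 0).
#' @param tolerance half-width of the band around 1 treated as
#'   non-cooperative (default 0.1).
#' @return `"positive"`, `"negative"` or `"noncooperative"`.
#' @export
classify_cooperativity <- function(h, tolerance = 0.1) {
  if (h <= 0) stop_domain("h must be positive")
  if (h > 1 + tolerance) "positive"
  else if (h < 1 - tolerance) "negative"
  else "noncooperative"
}
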