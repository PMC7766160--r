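#' TCSPC decay trace
#'
#' Photon-count histogram from time-correlated single-photon counting.
#' Times must ascend on a uniform grid; counts are non-negative integers.
#'
#' @param times ns, ascending, uniform spacing.
#' @param counts photon counts.
#' @param ligand_total mol/L, the titration point the trace belongs to.
#' @return Object of class `decay_trace`.
#' @export
decay_trace <- function(times, counts, ligand_total = NA_real_) {
  times <- as.numeric(times)
  counts <- as.numeric(counts)
  if (length(times) != length(counts))
    stop_domain("times and counts must have equal length")
  if (length(times) < 50) stop_domain("need >= 50 channels")
  dt <- diff(times)
  if (any(dt <= 0) || max(dt) - min(dt) > 1e-9 * max(dt))
    stop_domain("times must ascend on a uniform grid")
  if (any(counts < 0)) stop_domain("counts must be non-negative")
  structure(list(times = times, counts = counts, ligand_total = ligand_total),
            class = "decay_trace")
}

#' @export
print.decay_trace <- function(x, ...) {
  cat(sprintf("<decay_trace> %d channels, dt = %.3g ns, peak %d counts\n",
              length(x$times), x$times[2] - x$times[1], max(x$counts)))
  invisible(x)
}

#' Intensity-weighted average lifetime
#'
#' `tau_avg = sum(alpha_i * tau_i^2) / sum(alpha_i * tau_i)`: the
#' intensity-weighted mean of a multiexponential decay's component
#' lifetimes. Invariant under rescaling of all amplitudes; always lies
#' within `[min(tau), max(tau)]`.
#'
#' @param components a list of `c(alpha, tau)` pairs, or a 2-column
#'   matrix/data.frame with columns alpha, tau (ns).
#' @return tau_avg in ns.
#' @export
average_lifetime <- function(components) {
  m <- components_matrix(components)
  if (nrow(m) == 0) stop_domain("empty component list")
  if (any(m[, 1] <= 0) || any(m[, 2] <= 0))
    stop_domain("amplitudes and lifetimes must be positive")
  sum(m[, 1] * m[, 2]^2) / sum(m[, 1] * m[, 2])
}

components_matrix <- function(components) {
  if (is.data.frame(components)) components <- as.matrix(components)
  if (is.list(components) && !is.matrix(components))
    components <- do.call(rbind, components)
  m <- matrix(as.numeric(components), ncol = 2)
  colnames(m) <- c("alpha", "tau")
  m
}

#' Fit a multiexponential decay
#'
#' Tail-fits `I(t) = sum_i alpha_i exp(-t/tau_i)` from the peak channel
#' onward by weighted nonlinear least squares with Poisson weights
#' `1/max(count, 1)`. The model order is chosen as the smallest number of
#' components whose reduced chi-squared improves on the next lower order
#' by less than `improvement` (default 10%). Amplitudes are renormalized
#' to sum to 1.
#'
#' @param trace a [decay_trace].
#' @param max_components 1, 2 or 3.
#' @param improvement fractional reduced-chi2 improvement below which an
#'   extra component is not accepted.
#' @return Object of class `decay_fit`: `components` (data frame alpha,
#'   tau), `tau_avg` (ns), `chi2_reduced`, `n_components`, `ligand_total`.
#' @export
fit_decay <- function(trace, max_components = 3, improvement = 0.10) {
  if (!max_components %in% 1:3) stop_domain("max_components must be 1, 2 or 3")
  ipk <- which.max(trace$counts)
  t <- trace$times[ipk:length(trace$times)]
  y <- trace$counts[ipk:length(trace$counts)]
  t <- t - t[1]
  # require a decaying signal above background: compare early and late deciles
  n <- length(y)
  early <- mean(y[seq_len(max(5, n %/% 10))])
  late <- mean(y[seq(n - max(5, n %/% 10) + 1, n)])
  if (!is.finite(early) || early < 2 * late + 5)
    stop_fit("no decaying signal above background in trace")
  w <- 1 / pmax(y, 1)

  fit_order <- function(k) {
    # start values: log-linear fit for tau scale, split geometrically
    pos <- y > 0
    tau0 <- tryCatch({
      lf <- lm(log(y[pos]) ~ t[pos])
      max(-1 / coef(lf)[2], t[2])
    }, error = function(e) max(t) / 5)
    taus <- tau0 * 2^(seq_len(k) - (k + 1) / 2)
    A0 <- max(y)
    start <- as.list(c(setNames(rep(A0 / k, k), paste0("A", seq_len(k))),
                       setNames(taus, paste0("tau", seq_len(k)))))
    form <- paste0("A", seq_len(k), " * exp(-t/tau", seq_len(k), ")",
                   collapse = " + ")
    tryCatch(
      nlsLM(as.formula(paste("y ~", form)),
            data = data.frame(t = t, y = y),
            start = start, weights = w,
            lower = rep(c(0, min(diff(t))/10), each = k),
            control = nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
  }

  fits <- list()
  chi2 <- rep(NA_real_, max_components)
  for (k in seq_len(max_components)) {
    f <- fit_order(k)
    fits[[k]] <- f
    if (!is.null(f))
      chi2[k] <- sum(w * resid(f)^2) / (length(y) - 2 * k)
  }
  if (all(is.na(chi2))) stop_fit("decay fit failed at all model orders")
  # smallest order whose improvement over the previous is < threshold
  chosen <- which(!is.na(chi2))[1]
  for (k in seq_len(max_components - 1)) {
    if (is.na(chi2[k]) || is.na(chi2[k + 1])) break
    if ((chi2[k] - chi2[k + 1]) / chi2[k] >= improvement) chosen <- k + 1
    else break
  }
  f <- fits[[chosen]]
  p <- coef(f)
  A <- p[paste0("A", seq_len(chosen))]
  tau <- p[paste0("tau", seq_len(chosen))]
  ord <- order(tau)
  A <- A[ord]; tau <- tau[ord]
  alpha <- A / sum(A)
  comp <- data.frame(alpha = unname(alpha), tau = unname(tau))
  structure(list(
    components = comp,
    tau_avg = average_lifetime(comp),
    chi2_reduced = chi2[chosen],
    n_components = chosen,
    ligand_total = trace$ligand_total), class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> %d component(s), tau_avg = %.3g ns, red. chi2 = %.3g\n",
              x$n_components, x$tau_avg, x$chi2_reduced))
  invisible(x)
}

#' Read a decay trace CSV
#'
#' Columns `time_ns`, `counts`; metadata `# ligand_total:` (mol/L).
#'
#' @param path file path.
#' @return A [decay_trace].
#' @export
read_decay <- function(path) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  lines <- readLines(path)
  meta <- parse_metadata(grep("^#", lines, value = TRUE))
  body <- lines[!grepl("^#", lines)]
  df <- read.csv(text = paste(body[nzchar(trimws(body))], collapse = "\n"))
  if (!all(c("time_ns", "counts") %in% names(df)))
    stop_format("decay file needs columns time_ns, counts")
  decay_trace(df$time_ns, df$counts,
              ligand_total = as.numeric(meta$ligand_total %||% NA))
}
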