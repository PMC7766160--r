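#' Analysis configuration
#'
#' Validated flat configuration for [run_pipeline()]. Either a simulation
#' block (the default) or paths to titration/decay CSV files.
#'
#' @param simulate logical; simulate the study from a [ground_truth]
#'   rather than reading files.
#' @param seed integer; seeds every stochastic component.
#' @param truth a [ground_truth] (built from `seed` if NULL).
#' @param titration_files,decay_files input CSVs when `simulate = FALSE`.
#'   Titration files must cover the binding temperatures at one protein
#'   concentration and the IDF protein series at `idf_temperature`.
#' @param temperatures K, binding-equilibrium titration temperatures.
#' @param protein_totals mol/L, IDF protein series.
#' @param ligand_grid mol/L titration grid (simulation only).
#' @param idf_temperature K at which the binding-density analysis runs.
#' @param k_q_threshold,lifetime_tolerance,coop_tolerance,idf_levels
#'   analysis thresholds (diffusion limit M^-1 s^-1; relative lifetime
#'   tolerance; Hill-coefficient band; quench-grid size).
#' @param outdir optional output directory for the JSON report and tables.
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(simulate = TRUE,
                            seed = 20201218,
                            truth = NULL,
                            titration_files = character(),
                            decay_files = character(),
                            temperatures = c(288, 298, 308),
                            protein_totals = c(4e-6, 6e-6, 8e-6),
                            ligand_grid = seq(0, 20e-6, by = 0.5e-6),
                            idf_temperature = 288,
                            k_q_threshold = 1e10,
                            lifetime_tolerance = 0.05,
                            coop_tolerance = 0.1,
                            idf_levels = 15,
                            outdir = NULL) {
  stopifnot(k_q_threshold > 0, lifetime_tolerance > 0, coop_tolerance > 0,
            idf_levels >= 5)
  if (!simulate) {
    missing <- titration_files[!file.exists(titration_files)]
    if (length(missing)) stop_format("missing input files: ",
                                     paste(missing, collapse = ", "))
  }
  if (is.null(truth)) truth <- ground_truth(seed = seed)
  structure(list(simulate = simulate, seed = as.integer(seed), truth = truth,
                 titration_files = titration_files, decay_files = decay_files,
                 temperatures = temperatures, protein_totals = protein_totals,
                 ligand_grid = ligand_grid, idf_temperature = idf_temperature,
                 k_q_threshold = k_q_threshold,
                 lifetime_tolerance = lifetime_tolerance,
                 coop_tolerance = coop_tolerance, idf_levels = idf_levels,
                 outdir = outdir), class = "analysis_config")
}

#' Read a flat key-value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. List-valued
#' keys (`temperatures`, `protein_totals`, `titration_files`,
#' `decay_files`) take comma-separated values.
#'
#' @param path file path.
#' @return An [analysis_config].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_format("config file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- lines[grepl("=", lines)]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    kv[[trimws(parts[1])]] <- trimws(paste(parts[-1], collapse = "="))
  }
  num <- function(x) if (is.null(x)) NULL else as.numeric(strsplit(x, ",")[[1]])
  chr <- function(x) if (is.null(x)) character() else trimws(strsplit(x, ",")[[1]])
  args <- list()
  if (!is.null(kv$simulate)) args$simulate <- tolower(kv$simulate) %in% c("true", "yes", "1")
  for (key in c("seed", "idf_temperature", "k_q_threshold",
                "lifetime_tolerance", "coop_tolerance", "idf_levels"))
    if (!is.null(kv[[key]])) args[[key]] <- num(kv[[key]])
  for (key in c("temperatures", "protein_totals", "ligand_grid"))
    if (!is.null(kv[[key]])) args[[key]] <- num(kv[[key]])
  for (key in c("titration_files", "decay_files"))
    if (!is.null(kv[[key]])) args[[key]] <- chr(kv[[key]])
  if (!is.null(kv$outdir)) args$outdir <- kv$outdir
  do.call(analysis_config, args)
}

run_stage <- function(report, name, expr) {
  res <- tryCatch(list(ok = TRUE, value = expr),
                  error = function(e) list(ok = FALSE, error = conditionMessage(e)))
  if (res$ok) {
    report$stages[[name]] <- list(status = "ok")
    report[[name]] <- res$value
  } else {
    report$stages[[name]] <- list(status = "failed", error = res$error)
    warning(sprintf("stage '%s' failed: %s", name, res$error), call. = FALSE)
  }
  report
}

#' Run the full binding-characterization pipeline
#'
#' Sequences the study the way the bench workflow runs: simulate or load
#' titrations, inner-filter correction, Stern-Volmer fits per temperature,
#' lifetime fits across the titration and the quenching-mechanism call,
#' double-log binding constants per temperature, van't Hoff decomposition
#' with Gibbs energies and driving-force classification, and the
#' binding-density (IDF) analysis with Scatchard and Hill fits at the IDF
#' temperature. Stage failures are recorded in the report and do not
#' silently drop later stages that can still run.
#'
#' @param config an [analysis_config].
#' @return Object of class `study_report`.
#' @export
run_pipeline <- function(config) {
  report <- list(stages = list(), config = config_fingerprint(config))
  truth <- config$truth

  # ---- data acquisition -------------------------------------------------
  if (config$simulate) {
    binding_series <- lapply(seq_along(config$temperatures), function(i)
      simulate_titration(truth, config$protein_totals[1],
                         config$temperatures[i], config$ligand_grid,
                         seed_offset = i))
    idf_series <- lapply(seq_along(config$protein_totals), function(j)
      simulate_titration(truth, config$protein_totals[j],
                         config$idf_temperature, config$ligand_grid,
                         seed_offset = 100 + j))
    decay_ligands <- seq(0, max(config$ligand_grid), length.out = 5)
    decays <- lapply(seq_along(decay_ligands), function(i)
      simulate_decay(truth, decay_ligands[i], seed_offset = i))
  } else {
    all_series <- lapply(config$titration_files, read_titration)
    temps <- vapply(all_series, function(s) s$temperature, 0)
    prots <- vapply(all_series, function(s) s$protein_total, 0)
    binding_series <- all_series[match(config$temperatures, temps)]
    if (any(vapply(binding_series, is.null, TRUE)))
      stop_data("no titration file for every binding temperature")
    idf_series <- all_series[temps == config$idf_temperature &
                               prots %in% config$protein_totals]
    decays <- lapply(config$decay_files, read_decay)
  }
  binding_series <- lapply(binding_series, correct_series)
  idf_series <- lapply(idf_series, correct_series)

  # ---- quenching --------------------------------------------------------
  report <- run_stage(report, "stern_volmer", lapply(binding_series, fit_stern_volmer))
  report <- run_stage(report, "lifetimes", lapply(decays, fit_decay))
  if (!is.null(report$lifetimes) && length(report$lifetimes)) {
    tau0 <- report$lifetimes[[1]]$tau_avg
    report <- run_stage(report, "mechanism",
      classify_mechanism(report$stern_volmer, report$lifetimes, tau0,
                         k_q_threshold = config$k_q_threshold,
                         lifetime_tolerance = config$lifetime_tolerance))
    report$tau0 <- tau0
  }

  # ---- binding equilibrium + thermodynamics ----------------------------
  report <- run_stage(report, "double_log", lapply(binding_series, fit_double_log))
  if (!is.null(report$double_log)) {
    ka <- data.frame(
      temperature = vapply(report$double_log, function(f) f$temperature, 0),
      K_a = vapply(report$double_log, function(f) f$K_a, 0))
    report <- run_stage(report, "vant_hoff", {
      if (nrow(ka) < 2) stop_data("need >= 2 temperatures for van't Hoff")
      fit_vant_hoff(ka)
    })
    if (!is.null(report$vant_hoff)) {
      report$gibbs <- gibbs_energy(report$vant_hoff, ka$temperature)
      report$driving_forces <- classify_driving_forces(
        report$vant_hoff$delta_H, report$vant_hoff$delta_S)
    }
  }

  # ---- binding density / cooperativity ---------------------------------
  report <- run_stage(report, "saturation", lapply(idf_series, function(s) {
    Fc <- series_intensities(s)
    pts <- data.frame(ligand_total = s$records$ligand_total,
                      deltaF = delta_F(Fc, Fc[1]))
    fit_saturation(pts, s$protein_total)
  }))
  if (!is.null(report$saturation)) {
    report <- run_stage(report, "binding_density",
      binding_density(report$saturation, n_levels = config$idf_levels))
    if (!is.null(report$binding_density)) {
      report <- run_stage(report, "scatchard", scatchard(report$binding_density))
      report <- run_stage(report, "hill", fit_hill(report$binding_density))
      if (!is.null(report$hill))
        report$cooperativity <- classify_cooperativity(report$hill$h,
                                                       config$coop_tolerance)
    }
  }

  class(report) <- "study_report"
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    write_report_json(report, file.path(config$outdir, "report.json"))
    writeLines(render_tables(report), file.path(config$outdir, "tables.txt"))
  }
  report
}

# Cheap deterministic fingerprint of everything in the config except the
# output location, so reports record what produced them.
config_fingerprint <- function(config) {
  txt <- paste(deparse(config[setdiff(names(config), "outdir")]), collapse = "")
  codes <- utf8ToInt(txt)
  sprintf("cfg-%08x", sum(codes * (seq_along(codes) %% 251)) %% 4294967291)
}

#' Serialize a study report to JSON
#'
#' Deterministic (no timestamps): rerunning an identical configuration
#' produces a byte-identical file.
#'
#' @param report a `study_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  out <- list(
    config = report$config,
    stages = report$stages,
    stern_volmer = lapply(report$stern_volmer, function(f)
      list(temperature = f$temperature, K_SV = f$K_SV,
           stderr = f$stderr_K_SV, intercept = f$intercept,
           r_squared = f$r_squared)),
    tau0_ns = report$tau0,
    mechanism = if (!is.null(report$mechanism))
      list(call = report$mechanism$mechanism,
           ksv_trend = report$mechanism$ksv_temperature_trend,
           k_q = as.list(report$mechanism$k_q_values)),
    double_log = lapply(report$double_log, function(f)
      list(temperature = f$temperature, K_a = f$K_a, n = f$n_stoich,
           r_squared = f$r_squared)),
    thermodynamics = if (!is.null(report$vant_hoff))
      list(delta_H_J = report$vant_hoff$delta_H,
           delta_S_J = report$vant_hoff$delta_S,
           gibbs = report$gibbs,
           driving_forces = report$driving_forces),
    binding_density = if (!is.null(report$binding_density))
      as.data.frame(report$binding_density),
    scatchard = if (!is.null(report$scatchard))
      list(classification = report$scatchard$classification,
           quadratic_coefficient = report$scatchard$quadratic_coefficient),
    hill = if (!is.null(report$hill))
      list(n_sites = report$hill$n_sites, K_b = report$hill$K_b,
           h = report$hill$h, cooperativity = report$cooperativity))
  write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null",
             pretty = TRUE)
  invisible(path)
}

#' Render report tables
#'
#' Fixed-width text tables mirroring how binding studies tabulate their
#' results: one table of Stern-Volmer, bimolecular and binding constants
#' per temperature, and one thermodynamics table with T, dG, dH and T*dS
#' in kJ/mol. Missing stages are omitted with a note.
#'
#' @param report a `study_report`.
#' @return Character vector of lines.
#' @export
render_tables <- function(report) {
  lines <- character()
  if (length(report$stern_volmer) || length(report$double_log)) {
    lines <- c(lines,
      "Quenching and binding constants",
      sprintf("%-8s %-18s %-22s %-16s",
              "T (K)", "K_SV (10^4 M^-1)", "k_q (10^12 M^-1 s^-1)", "K_a (10^5 M^-1)"))
    temps <- vapply(report$stern_volmer, function(f) f$temperature, 0)
    for (i in seq_along(temps)) {
      ksv <- report$stern_volmer[[i]]$K_SV
      kq <- if (!is.null(report$tau0))
        bimolecular_constant(ksv, report$tau0 * 1e-9) else NA
      ka <- if (length(report$double_log) >= i) report$double_log[[i]]$K_a else NA
      lines <- c(lines, sprintf("%-8.0f %-18.2f %-22.2f %-16.2f",
                                temps[i], ksv / 1e4, kq / 1e12, ka / 1e5))
    }
    lines <- c(lines, "")
  } else {
    lines <- c(lines, "Quenching stage unavailable; table omitted.", "")
  }
  if (!is.null(report$vant_hoff)) {
    vh <- report$vant_hoff
    lines <- c(lines,
      "Thermodynamic parameters",
      sprintf("%-8s %-14s %-14s %-14s",
              "T (K)", "dG (kJ/mol)", "dH (kJ/mol)", "T.dS (kJ/mol)"))
    for (i in seq_len(nrow(report$gibbs))) {
      Tk <- report$gibbs$temperature[i]
      lines <- c(lines, sprintf("%-8.0f %-14.2f %-14.2f %-14.2f",
                                Tk, report$gibbs$delta_G[i] / 1000,
                                vh$delta_H / 1000, Tk * vh$delta_S / 1000))
    }
    lines <- c(lines, sprintf("Driving forces: %s", report$driving_forces), "")
  } else {
    lines <- c(lines, "Thermodynamics stage unavailable; table omitted.", "")
  }
  if (!is.null(report$hill)) {
    lines <- c(lines, "Cooperativity (binding-density route)",
      sprintf("  n = %.2f sites, K_b = %.3g M^-1, h = %.2f (%s); Scatchard: %s",
              report$hill$n_sites, report$hill$K_b, report$hill$h,
              report$cooperativity,
              if (!is.null(report$scatchard)) report$scatchard$classification
              else "unavailable"))
  } else if (length(lines) == 0) {
    lines <- "Empty report: no stages completed."
  }
  lines
}

#' @export
print.study_report <- function(x, ...) {
  cat(render_tables(x), sep = "\n")
  invisible(x)
}

#' Full-pipeline parameter-recovery study
#'
#' Simulates titrations at every (protein, temperature) pair of the
#' study grid, runs the binding-density analysis at each temperature, and
#' refits Hill with the site count shared across temperatures
#' ([fit_hill_global()]); the per-temperature Hill constants then feed a
#' weighted van't Hoff fit. Used to quantify how well the model-free
#' pipeline recovers the generative thermodynamics and cooperativity.
#'
#' @param truth a [ground_truth].
#' @param protein_totals mol/L.
#' @param temperatures K.
#' @param ligand_grid mol/L.
#' @param n_levels quench-grid size.
#' @return List: `hill_by_T` (per-temperature [fit_hill()]),
#'   `scatchard_by_T`, `global` ([fit_hill_global()] result), `thermo`
#'   ([fit_vant_hoff()] on the global per-temperature constants),
#'   `binding_density_by_T`.
#' @export
recovery_study <- function(truth,
                           protein_totals = c(4e-6, 6e-6, 8e-6),
                           temperatures = c(288, 298, 308),
                           ligand_grid = seq(0, 20e-6, by = 0.5e-6),
                           n_levels = 15) {
  bd_by_T <- lapply(seq_along(temperatures), function(i) {
    curves <- lapply(seq_along(protein_totals), function(j) {
      s <- correct_series(simulate_titration(
        truth, protein_totals[j], temperatures[i], ligand_grid,
        seed_offset = 10 * i + j))
      Fc <- s$records$F_corr
      fit_saturation(data.frame(ligand_total = s$records$ligand_total,
                                deltaF = delta_F(Fc, Fc[1])),
                     s$protein_total)
    })
    binding_density(curves, n_levels = n_levels)
  })
  hill_by_T <- lapply(bd_by_T, function(bd)
    tryCatch(fit_hill(bd), error = function(e) NULL))
  scat_by_T <- lapply(bd_by_T, function(bd)
    tryCatch(scatchard(bd), error = function(e) NULL))
  glob <- fit_hill_global(bd_by_T)
  thermo <- fit_vant_hoff(data.frame(temperature = temperatures,
                                     K_a = glob$per_dataset$K_b))
  list(binding_density_by_T = bd_by_T, hill_by_T = hill_by_T,
       scatchard_by_T = scat_by_T, global = glob, thermo = thermo,
       temperatures = temperatures)
}
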