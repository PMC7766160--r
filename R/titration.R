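#' Ligand titration series
#'
#' One protein concentration and temperature's ligand titration. Records are
#' stored as a data frame with columns `ligand_total` (mol/L), `F_raw`,
#' `A_ex`, `A_em` and, once [correct_series()] has been applied, `F_corr`.
#' The first record must have zero ligand: its corrected intensity defines
#' `F0`, the unquenched reference used by all downstream analyses.
#'
#' @param protein_total mol/L.
#' @param temperature K.
#' @param records data frame with columns `ligand_total`, `F_raw`, `A_ex`,
#'   `A_em` (and optionally `F_corr`).
#' @return An object of class `titration_series`.
#' @export
titration_series <- function(protein_total, temperature, records) {
  required <- c("ligand_total", "F_raw", "A_ex", "A_em")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols))
    stop_format("missing required columns: ", paste(missing_cols, collapse = ", "))
  records <- as.data.frame(records)
  if (nrow(records) < 1) stop_format("empty titration")
  if (records$ligand_total[1] != 0)
    stop_format("first record must have ligand_total = 0 (defines F0)")
  if (any(diff(records$ligand_total) <= 0)) {
    bad <- which(diff(records$ligand_total) <= 0)[1] + 1
    stop_format("ligand_total must be strictly increasing; offending row ", bad)
  }
  for (cl in required) {
    if (any(!is.finite(records[[cl]])) || any(records[[cl]] < 0)) {
      bad <- which(!is.finite(records[[cl]]) | records[[cl]] < 0)[1]
      stop_format(cl, " must be finite and non-negative; offending row ", bad)
    }
  }
  if (!is.finite(protein_total) || protein_total <= 0)
    stop_domain("protein_total must be positive")
  if (!"F_corr" %in% names(records)) records$F_corr <- NA_real_
  structure(list(protein_total = protein_total, temperature = temperature,
                 records = records),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("<titration_series> P = %.3g M, T = %.0f K, %d records (L = 0 to %.3g M)\n",
              x$protein_total, x$temperature, nrow(x$records),
              max(x$records$ligand_total)))
  invisible(x)
}

#' Inner-filter correction
#'
#' Corrects observed fluorescence for attenuation of the excitation and
#' emission beams by absorbing species in the cuvette:
#' `F_corr = F_obs * 10^((5 * A_ex + A_em) / 10)`. The unequal weighting of
#' the two absorbances reflects the 10 x 2 mm cuvette geometry, with
#' absorbances read on a 10 mm path.
#'
#' @param F_obs observed fluorescence, arbitrary units.
#' @param A_ex absorbance at the excitation wavelength (10 mm path).
#' @param A_em absorbance at the emission wavelength (10 mm path).
#' @return Corrected fluorescence; equals `F_obs` when both absorbances
#'   are zero. Vectorized.
#' @export
correct_inner_filter <- function(F_obs, A_ex, A_em) {
  if (any(F_obs < 0) || any(A_ex < 0) || any(A_em < 0))
    stop_domain("F_obs, A_ex and A_em must be non-negative")
  F_obs * 10^((5 * A_ex + A_em) / 10)
}

#' Apply the inner-filter correction to a titration series
#'
#' Fills the `F_corr` column from `F_raw`, `A_ex` and `A_em`.
#'
#' @param series a [titration_series].
#' @return The series with `F_corr` populated.
#' @export
correct_series <- function(series) {
  r <- series$records
  series$records$F_corr <- correct_inner_filter(r$F_raw, r$A_ex, r$A_em)
  series
}

# Corrected intensities of a series, computing them on the fly if absent.
series_intensities <- function(series) {
  Fc <- series$records$F_corr
  if (any(!is.finite(Fc))) Fc <- correct_series(series)$records$F_corr
  Fc
}

#' Percentage fluorescence change
#'
#' `delta_F = |F - F0| / F0 * 100`, the percent change of the (corrected)
#' fluorescence signal relative to the zero-ligand reference. Scale
#' invariant in (F, F0).
#'
#' @param F fluorescence at a titration point.
#' @param F0 zero-ligand reference fluorescence, `> 0`.
#' @return Percent change (non-negative). Vectorized over `F`.
#' @export
delta_F <- function(F, F0) {
  if (any(F0 <= 0)) stop_domain("F0 must be positive")
  abs(F - F0) / F0 * 100
}

#' Read a titration CSV
#'
#' Expects comma-separated columns `ligand_total`, `F_raw`, `A_ex`, `A_em`
#' (optionally `F_corr`) preceded by `#`-prefixed metadata lines:
#' `# protein_total:`, `# temperature:` and `# units:` (`M` or `uM`).
#' Concentrations declared in `uM` are converted to mol/L on read.
#'
#' @param path file path.
#' @return A [titration_series].
#' @export
read_titration <- function(path) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- parse_metadata(meta_lines)
  for (key in c("protein_total", "temperature"))
    if (is.null(meta[[key]]))
      stop_format("missing metadata line '# ", key, ":' in ", path)
  units <- tolower(meta$units %||% "m")
  if (!units %in% c("m", "um"))
    stop_format("unknown units '", meta$units, "' (use M or uM)")
  scale <- if (units == "um") 1e-6 else 1
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  df <- read.csv(text = paste(body, collapse = "\n"))
  required <- c("ligand_total", "F_raw", "A_ex", "A_em")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop_format("missing required columns: ", paste(missing_cols, collapse = ", "))
  df$ligand_total <- df$ligand_total * scale
  titration_series(protein_total = as.numeric(meta$protein_total) * scale,
                   temperature = as.numeric(meta$temperature),
                   records = df)
}

#' Write a titration CSV
#'
#' Writes the [read_titration()] dialect (always in mol/L with
#' `# units: M`), with full double precision so that a write/read
#' round-trip reproduces every numeric field exactly.
#'
#' @param series a [titration_series].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_titration <- function(series, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# protein_total: %.17g", series$protein_total),
    sprintf("# temperature: %.17g", series$temperature),
    "# units: M"), con)
  r <- series$records
  cols <- c("ligand_total", "F_raw", "A_ex", "A_em")
  if (any(is.finite(r$F_corr))) cols <- c(cols, "F_corr")
  writeLines(paste(cols, collapse = ","), con)
  for (i in seq_len(nrow(r)))
    writeLines(paste(vapply(r[i, cols], function(v) sprintf("%.17g", v), ""),
                     collapse = ","), con)
  invisible(path)
}

parse_metadata <- function(meta_lines) {
  out <- list()
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) out[[m[2]]] <- trimws(m[3])
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an emission or CD spectrum CSV
#'
#' Emission files have columns `wavelength_nm`, `intensity`; CD files have
#' `wavelength_nm`, `theta_mdeg` plus metadata `# path_cm:`,
#' `# n_residues:` and `# protein_total:` (mol/L).
#'
#' @param path file path.
#' @return An [emission_spectrum] or [cd_spectrum] depending on columns.
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) stop_format("file not found: ", path)
  lines <- readLines(path)
  meta <- parse_metadata(grep("^#", lines, value = TRUE))
  body <- lines[!grepl("^#", lines)]
  df <- read.csv(text = paste(body[nzchar(trimws(body))], collapse = "\n"))
  if ("theta_mdeg" %in% names(df)) {
    for (key in c("path_cm", "n_residues", "protein_total"))
      if (is.null(meta[[key]]))
        stop_format("missing metadata line '# ", key, ":' in ", path)
    cd_spectrum(df$wavelength_nm, df$theta_mdeg,
                protein_total = as.numeric(meta$protein_total),
                path_length = as.numeric(meta$path_cm),
                n_residues = as.numeric(meta$n_residues),
                molar_ratio_label = meta$molar_ratio %||% "")
  } else if ("intensity" %in% names(df)) {
    emission_spectrum(df$wavelength_nm, df$intensity,
                      temperature = as.numeric(meta$temperature %||% NA),
                      protein_total = as.numeric(meta$protein_total %||% NA),
                      ligand_total = as.numeric(meta$ligand_total %||% NA))
  } else {
    stop_format("unrecognized spectrum columns in ", path)
  }
}
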