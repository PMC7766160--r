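#' Emission spectrum
#'
#' Container for a steady-state fluorescence emission spectrum recorded at a
#' single (protein, ligand, temperature) condition. Wavelengths must be
#' strictly increasing and intensities non-negative.
#'
#' @param wavelengths numeric, nm, strictly increasing.
#' @param intensities numeric, arbitrary fluorescence units, `>= 0`.
#' @param temperature K.
#' @param protein_total total protein concentration, mol/L.
#' @param ligand_total total ligand concentration, mol/L.
#' @return An object of class `emission_spectrum`.
#' @export
emission_spectrum <- function(wavelengths, intensities, temperature = NA_real_,
                              protein_total = NA_real_, ligand_total = NA_real_) {
  wavelengths <- as.numeric(wavelengths)
  intensities <- as.numeric(intensities)
  if (length(wavelengths) != length(intensities))
    stop_domain("wavelengths and intensities must have equal length")
  if (length(wavelengths) > 1 && any(diff(wavelengths) <= 0))
    stop_domain("wavelengths must be strictly increasing")
  if (any(intensities < 0))
    stop_domain("intensities must be non-negative")
  structure(
    list(wavelengths = wavelengths, intensities = intensities,
         temperature = temperature, protein_total = protein_total,
         ligand_total = ligand_total),
    class = "emission_spectrum")
}

#' @export
print.emission_spectrum <- function(x, ...) {
  cat(sprintf("<emission_spectrum> %d points, %.0f-%.0f nm\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Circular dichroism spectrum
#'
#' @param wavelengths nm.
#' @param theta_mdeg ellipticity, millidegrees.
#' @param protein_total mol/L.
#' @param path_length cuvette path, cm (CD cells are typically 0.01 cm).
#' @param n_residues number of amino-acid residues; required for conversion
#'   to mean residue ellipticity and never defaulted.
#' @param molar_ratio_label free-text label such as `"1:2.5"`.
#' @return An object of class `cd_spectrum`.
#' @export
cd_spectrum <- function(wavelengths, theta_mdeg, protein_total, path_length,
                        n_residues, molar_ratio_label = "") {
  wavelengths <- as.numeric(wavelengths)
  theta_mdeg <- as.numeric(theta_mdeg)
  if (length(wavelengths) != length(theta_mdeg))
    stop_domain("wavelengths and theta_mdeg must have equal length")
  if (!is.finite(path_length) || path_length <= 0)
    stop_domain("path_length must be positive")
  if (!is.finite(n_residues) || n_residues < 1)
    stop_domain("n_residues must be >= 1")
  structure(
    list(wavelengths = wavelengths, theta_mdeg = theta_mdeg,
         protein_total = protein_total, path_length = path_length,
         n_residues = n_residues, molar_ratio_label = molar_ratio_label),
    class = "cd_spectrum")
}

#' @export
print.cd_spectrum <- function(x, ...) {
  cat(sprintf("<cd_spectrum> %d points, %.0f-%.0f nm, ratio '%s'\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              x$molar_ratio_label))
  invisible(x)
}

#' Band intensity of an emission spectrum
#'
#' Reads the fluorescence intensity at a band center: the nearest grid point
#' when `window = 0`, otherwise the mean intensity over
#' `center +/- window/2`. The tryptophan band of a single-Trp protein is
#' conventionally read at 330 nm.
#'
#' @param spectrum an [emission_spectrum].
#' @param center nm; must lie inside the recorded wavelength range.
#' @param window nm; averaging window width (0 = single nearest point).
#' @return Intensity in the spectrum's units.
#' @export
band_intensity <- function(spectrum, center, window = 0) {
  wl <- spectrum$wavelengths
  if (center < min(wl) || center > max(wl))
    stop_range(sprintf("band center %.1f nm outside spectral range [%.1f, %.1f]",
                       center, min(wl), max(wl)))
  if (window <= 0) {
    spectrum$intensities[which.min(abs(wl - center))]
  } else {
    sel <- wl >= center - window / 2 & wl <= center + window / 2
    mean(spectrum$intensities[sel])
  }
}

#' Full width at half maximum of an emission band
#'
#' Locates the band maximum nearest `center` and measures the width between
#' the two half-maximum crossings that bracket it, using linear
#' interpolation between grid points.
#'
#' @param spectrum an [emission_spectrum].
#' @param center nm, approximate band position.
#' @return FWHM in nm.
#' @export
band_fwhm <- function(spectrum, center) {
  wl <- spectrum$wavelengths
  y <- spectrum$intensities
  if (center < min(wl) || center > max(wl))
    stop_range("band center outside spectral range")
  # local maximum nearest the requested center
  ipk <- which.min(abs(wl - center))
  # climb to the local peak
  repeat {
    if (ipk > 1 && y[ipk - 1] > y[ipk]) ipk <- ipk - 1
    else if (ipk < length(y) && y[ipk + 1] > y[ipk]) ipk <- ipk + 1
    else break
  }
  half <- y[ipk] / 2
  left <- NA_real_
  if (ipk >= 2) {
    for (i in seq(ipk, 2L)) {
      if (y[i - 1] <= half && y[i] >= half) {
        left <- wl[i - 1] + (half - y[i - 1]) / (y[i] - y[i - 1]) * (wl[i] - wl[i - 1])
        break
      }
    }
  }
  right <- NA_real_
  if (ipk < length(y)) {
    for (i in seq(ipk, length(y) - 1L)) {
      if (y[i] >= half && y[i + 1] <= half) {
        right <- wl[i] + (y[i] - half) / (y[i] - y[i + 1]) * (wl[i + 1] - wl[i])
        break
      }
    }
  }
  if (!is.finite(left) || !is.finite(right))
    stop_fit("unresolved band: no half-maximum crossing on ",
             if (!is.finite(left)) "the left" else "the right",
             " side of the peak")
  right - left
}

#' Mean residue ellipticity
#'
#' Converts millidegree ellipticity to mean residue ellipticity,
#' `[theta] = theta_mdeg / (10 * P * l * n)` in deg cm^2 dmol^-1, where `P`
#' is the molar protein concentration, `l` the path length in cm and `n`
#' the residue count.
#'
#' @param spectrum a [cd_spectrum].
#' @return Numeric vector of mean residue ellipticities, one per wavelength.
#' @export
mean_residue_ellipticity <- function(spectrum) {
  P <- spectrum$protein_total
  l <- spectrum$path_length
  n <- spectrum$n_residues
  if (!is.finite(P) || P <= 0) stop_domain("protein_total must be positive")
  if (l <= 0) stop_domain("path_length must be positive")
  if (n <= 0) stop_domain("n_residues must be positive")
  spectrum$theta_mdeg / (10 * P * l * n)
}
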