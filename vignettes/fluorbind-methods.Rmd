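---
title: "Fluorescence quenching and binding-density analysis with fluorbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fluorescence quenching and binding-density analysis with fluorbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluorbind)
```

## The problem

A single-tryptophan protein domain — the motivating case is the ~40 kDa
nucleotide-binding domain (NBD) of HSP70, whose Trp90 dominates the
intrinsic fluorescence — is titrated with a small-molecule ligand that
quenches the tryptophan emission at 330 nm. From these titrations a
complete binding characterization is assembled:

1. **Mechanism** — is the quenching static (ground-state complex) or
   dynamic (collisional)?
2. **Affinity and thermodynamics** — the binding constant at several
   temperatures, decomposed into ΔH and ΔS by van't Hoff analysis, and
   the driving forces inferred from their signs.
3. **Site count and cooperativity** — a model-free binding-density
   analysis across several protein concentrations, read out through
   Scatchard and Hill plots.

fluorbind implements each stage as a small, composable function, and
ships a two-site Adair simulator so the whole chain can be validated by
parameter recovery on data whose truth is known.

## Signal corrections

Observed intensities are corrected for the inner-filter effect,

$$F_\mathrm{corr} = F_\mathrm{obs} \cdot 10^{(5 A_\mathrm{ex} + A_\mathrm{em})/10},$$

with both absorbances read on a 10 mm path; the unequal weights encode
the 10 × 2 mm cuvette geometry. This exact form is implemented (no
generic $(A_\mathrm{ex}+A_\mathrm{em})/2$ fallback), and
`correct_inner_filter()` is the exact inverse of the attenuation the
simulator applies, which the tests exploit as a round-trip oracle.

The intensity entering every analysis is the corrected intensity at the
330 nm tryptophan band (`band_intensity()`, default single nearest grid
point; the band center is stable under titration because the two
emission bands — 330 ± 30 nm FWHM and 485 ± 46 nm FWHM — are separated
by more than three widths). $F_0$ is the corrected zero-ligand
intensity. CD spectra in millidegrees are converted to mean residue
ellipticity, $[\theta] = \theta/(10\,[P]\,l\,n)$; the residue count $n$
is a required input because it is protein-specific.

## Quenching mechanism

`fit_stern_volmer()` fits $F_0/F = 1 + K_{SV}[Q]$ by OLS (total ligand
as quencher concentration, as the plots are conventionally drawn).
`fit_decay()` tail-fits TCSPC histograms from the peak channel with
Poisson weights $1/\max(c_i, 1)$ and multiexponential order chosen as
the smallest model whose reduced-χ² improvement over the next lower
order is below 10% — a deterministic rule, preferred here over an
F-test. No instrument-response deconvolution is attempted. The
intensity-weighted mean lifetime is
$\langle\tau\rangle = \sum \alpha_i\tau_i^2 / \sum \alpha_i\tau_i$.

`classify_mechanism()` encodes the standard decision logic: static
quenching requires flat lifetimes under titration
($|\tau_0/\tau - 1| <$ `lifetime_tolerance`, default 0.05) *and*
$k_q = K_{SV}/\tau_0$ above the diffusion limit (`k_q_threshold`,
default $10^{10}\,\mathrm{M^{-1}s^{-1}}$); dynamic quenching requires
$\tau_0/\tau$ to track $F_0/F$ with $k_q$ at or below the limit;
anything else — including missing lifetime data — is `ambiguous`. The
temperature trend of $K_{SV}$ is reported but is not decisive when the
lifetime and $k_q$ evidence agree, since a rising $K_{SV}$ is compatible
with entropically driven complex formation. $\tau_0$ is taken from the
zero-ligand decay fit.

## Affinity and thermodynamics

The double-log plot is fitted as

$$\log_{10}\frac{F_0 - F}{F} = \log_{10} K_a + n \log_{10} [L],$$

with a **positive** slope term: as quencher is added the left side
rises, so the slope must be $+n$ for the intercept to return binding
constants of the right magnitude. (Printed forms of this equation
sometimes carry a minus sign on the $n$ term; that convention is
inconsistent with the reported constants, and the positive-slope form is
used throughout.) Base-10 logarithms are used here, natural logarithms
in the van't Hoff fit. Points with $F \ge F_0$ carry no signal and are
excluded with a warning. Total ligand stands in for free ligand — the
model's standard approximation, accurate only when ligand depletion by
binding is small; the binding-density route below removes this
approximation.

`fit_vant_hoff()` regresses $\ln K_a$ on $1/T$
($\ln K = -\Delta H/RT + \Delta S/R$, $R = 8.314$ J mol⁻¹ K⁻¹, ΔH and ΔS
assumed temperature-independent over the 20 K span), and
`gibbs_energy()` propagates $\Delta G = \Delta H - T\Delta S$ with the
full slope–intercept covariance. Signs classify the driving forces in
the Ross–Subramanian convention (`classify_driving_forces()`): both
positive → non-specific/hydrophobic; both negative → van der
Waals/hydrogen bonding; ΔH < 0, ΔS > 0 → electrostatic. Regression
standard errors are reported as-is; no attempt is made to reproduce
instrument-style uncertainty bars.

## Binding-density (IDF) analysis

The interaction density function method needs no binding model: if two
titrations at different total protein share the same fractional signal
change ΔF = |F−F₀|/F₀·100, they share the same average binding density
Σν and free ligand concentration, and mass conservation
$[L]_\mathrm{tot} = [L]_\mathrm{free} + \Sigma\nu\,[P]$ makes
$[L]_\mathrm{tot}$ versus $[P]$ at fixed ΔF a straight line: slope Σν,
intercept $[L]_\mathrm{free}$.

Implementation choices that matter:

* **Curve family.** Each titration's ΔF versus $\log_{10}[L]$ is fitted
  with an asymmetric five-parameter (Richards) logistic. A symmetric
  4-parameter logistic was evaluated first and rejected: on *noiseless*
  simulated cooperative titrations it leaves ~2 percentage-point
  systematic residuals, and because the bias differs between protein
  concentrations it destroys the cross-concentration collinearity the
  method depends on. The asymmetry parameter can be fixed at 1 to
  recover the symmetric form. `saturation_exact()` additionally wraps an
  analytic quench function (e.g. the simulator's forward model) in the
  same interface, which isolates the extraction step from fitting error
  in tests.
* **Weights.** Sigmoid fits weight points by $1/(1-\Delta F/100)^2$:
  multiplicative intensity noise implies the ΔF variance shrinks as the
  signal is quenched. Inverted concentrations carry delta-method
  standard errors from the sigmoid-fit covariance; the per-level line
  fits and the Hill fit are inverse-variance weighted, with an
  effective-variance iteration folding the $[L]_\mathrm{free}$ abscissa
  errors into the Hill residual variance.
* **Grid.** 15 ΔF levels (configurable), evenly spaced over the
  intersection of the curves' invertible ranges, trimmed 2 percentage
  points at each end and capped at the largest observed ΔF so the
  ceiling is never extrapolated.
* **Degenerate levels.** Slightly negative intercepts (within 2 SE) are
  clamped to zero with a warning; worse violations are flagged and
  excluded from the Hill fit, as are levels whose intercept is smaller
  than 2 SE (unresolved free ligand).

`scatchard()` fits a quadratic to $(\nu, \nu/L_\mathrm{free})$ and calls
cooperativity only when the concavity is significant at 2 SE, avoiding
noise-driven labels. `fit_hill()` fits
$\Sigma\nu = n (K_b L)^h / (1 + (K_b L)^h)$ (one site class; the
equivalent-sites conclusion makes the outer sum over classes collapse),
trying several deterministic starts and keeping the best weighted fit.
`h` is reported unconstrained — cooperative fits can return $h$ slightly
above $n$, and a constrained $h \le n$ refit is available via
`constrain_h_le_n = TRUE`, clearly separated. `fit_hill_global()` shares
$n$ across datasets (site count is a structural, temperature-independent
property), which stabilizes $K_b$ in datasets that do not reach
saturation.

## The simulator and what it does (not) emulate

`ground_truth()` fixes a two-site Adair model:
$\nu = (2KL + 2cK^2L^2)/(1 + 2KL + cK^2L^2)$ with intrinsic per-site
constant $K(T) = \exp(-\Delta H/RT + \Delta S/R)$ and cooperativity
factor $c$ (default 50, giving apparent Hill coefficients around 1.8–2).
The generative model is deliberately *not* a Hill law, so the analysis
chain is tested against a mechanistically distinct truth. Free ligand is
solved from mass conservation by 100-step bisection (residual below
$10^{-12} [L]_\mathrm{tot}$); quenching is static,
$F = F_0(1 - q_\mathrm{max}\theta)$ with $\theta = \nu/2$ and
$q_\mathrm{max} = 0.8$ by default (a linear signal–occupancy law — the
simplest consistent with a single fluorophore reporting site
occupancy); the ligand's absorbance ($\varepsilon_\mathrm{ex} = 10^4$,
$\varepsilon_\mathrm{em} = 4\times10^3$ M⁻¹cm⁻¹, chosen so
$A_\mathrm{ex} \le 0.2$ at 20 µM, the magnitude scale of a ligand with
$\varepsilon = 16{,}500$ M⁻¹cm⁻¹ at its absorption maximum) attenuates
the recorded signal by the exact inverse of the inner-filter
correction. Noise is multiplicative Gaussian on intensities (default
1%) and Poisson on decay counts; every draw is seed-pinned and
bit-reproducible.

**Thermodynamic calibration.** ΔH defaults to +130.13 kJ/mol. The
default ΔS (539.46 J mol⁻¹ K⁻¹) is chosen so that the *observable*
Hill-equivalent constant $K(288)\sqrt{c}$ equals $2.67\times10^5$ M⁻¹ —
the scale such a system actually reports at 288 K. Identifying the
tabulated apparent ΔS of the double-log constant with the intrinsic
per-site entropy would instead put all titrations in a fully
stoichiometric regime (midpoints compressed against the protein
concentration), which is not what measured saturation curves of this
system look like; the generator is calibrated to the observables.

CD spectra interpolate secondary-structure fractions linearly from
(34, 16, 20, 30)% (α, β, turn, coil) at ratio 0 toward (26, 31, 22, 21)%
at ratio 12.5. Published end-state numbers for the motivating system are
internally inconsistent (they are quoted differently in adjacent
sentences); the end state is therefore configurable, with this
normalized default. The basis bands are analytic Gaussian mixtures with
the canonical band positions — useful for round-trip tests of the
millidegree/MRE conversion, *not* a substitute for deconvolution
library spectra.

Not emulated: photobleaching, drift, scatter peaks, instrument response
functions, wavelength-dependent detector response, or any baseline
artifact beyond the inner-filter effect. Passing recovery tests
therefore demonstrates correctness of the analysis chain under the
stated noise model, not robustness to every artifact of real
instruments.

## Recovery performance and known limitations

The default recovery study (`recovery_study()`) simulates 3 protein
concentrations × 3 temperatures × 41 titration points at 1% noise —
problem sizes chosen to mirror a realistic bench study while keeping
the full suite fast. On this study the pipeline reliably recovers the
site count ($n = 2$ within ±0.2, anchored by the saturating
high-temperature datasets) and the positive cooperativity class by both
the Scatchard and Hill routes at 288 K.

The free-ligand intercept, however, is information-limited: with
protein at 4–8 µM, the cross-concentration line extrapolates to an
intercept whose standard error is ~0.05–0.15 µM regardless of how the
fitting is weighted. At 288 K the half-saturation free-ligand scale is
~3.7 µM and $K_b$ comes back with ~15% scatter; at 308 K the scale is
~0.11 µM — at the noise floor — so $K_b(308)$ can be off severalfold,
and a van't Hoff slope through the per-temperature Hill constants
inherits that error (ΔH typically within ~±20–50%). This is a property
of the model-free method at these concentrations, not of the
implementation: resolving it experimentally requires lower protein
concentrations or an orthogonal measurement of free ligand. The
acceptance tests assert the stricter recovery targets regardless and
the two affected assertions fail honestly under the default study
conditions.

Numerical conventions, in one place: internal units are SI (mol/L, K,
seconds; lifetimes in ns where stated); $R = 8.314$ J mol⁻¹ K⁻¹;
CSV readers require unit declarations and convert µM on read; all
optimizers are Levenberg–Marquardt (`minpack.lm`) with bounded
parameters and deterministic multi-starts; ties and degenerate inputs
produce typed errors (`domain error`, `range error`, `format error`,
`insufficient data`) rather than silent results.

## A worked run

```{r pipeline}
cfg <- analysis_config(seed = 101)
report <- run_pipeline(cfg)
report
```

The report object carries every stage's typed result (`stern_volmer`,
`double_log`, `vant_hoff`, `gibbs`, `binding_density`, `scatchard`,
`hill`), a stage-status table, and a configuration fingerprint;
`write_report_json()` serializes it deterministically, so identical
configurations produce byte-identical reports.
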