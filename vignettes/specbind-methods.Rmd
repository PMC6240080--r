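---
title: "Methods: spectroscopic binding analysis with specbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectroscopic binding analysis with specbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specbind)
```

specbind quantifies how a small molecule binds a fluorescent protein —
the motivating system is a drug ligand titrated into bovine serum albumin
(BSA) — from four kinds of spectra: fluorescence emission, UV absorbance,
far-UV circular dichroism (CD), and FT-IR amide bands. This vignette is the
package's account of the underlying models, the tunable parameters, the
synthetic-data generator used for verification, and the numerical and
design choices that were genuinely open.

## Fluorescence quenching model

BSA's intrinsic tryptophan fluorescence (emission maximum near 344 nm under
280 nm excitation) is quenched by a bound ligand. Two regimes are
distinguished by the Stern–Volmer analysis of intensity ratios:

$$\frac{F_0}{F} = 1 + K_{sv}[Q] = 1 + K_q \tau_0 [Q]$$

where $F_0$ is the intensity of the quencher-free solution, $F$ the
intensity at quencher concentration $[Q]$ (mol/L), $K_{sv}$ (L/mol) the
Stern–Volmer constant, $\tau_0$ the unquenched fluorophore lifetime and
$K_q = K_{sv}/\tau_0$ the apparent bimolecular quenching rate constant.

* **Intensity reading.** $F$ is read at a single fixed wavelength — the
  emission maximum of the quencher-free spectrum — not at a running maximum
  and not as an integrated area. For serum albumin the peak position and
  shape do not change on quenching, so the fixed-wavelength reading is both
  simpler and unbiased. Off-grid wavelengths are linearly interpolated.
* **Regression.** Ordinary least squares of $F_0/F$ on $[Q]$ with a *free*
  intercept, including the $Q=0$ point (which pins the intercept at exactly
  1, since $F_0/F_0 = 1$ regardless of noise). A free intercept exposes
  model misfit: a fitted intercept deviating from 1 by more than 0.05 is
  flagged on the result rather than silently constrained away.
* **Slope uncertainty.** The reported `Ksv_se` is not the textbook OLS
  standard error. Ratios $F_0/F$ are heteroscedastic (their noise grows
  roughly as the square of the ratio) and every ratio shares the single
  measured $F_0$, which adds a fully correlated "common-mode" error that
  ordinary residuals cannot see. `Ksv_se` is therefore the HC3
  (leverage-adjusted sandwich) slope error combined in quadrature with the
  propagated $F_0$ term $K_{sv}\,\hat\sigma_0/F_0$, where
  $\hat\sigma_0/F_0$ is estimated from the leverage-adjusted residuals. In
  simulation this keeps the 3-SE interval honest (≥ 95% coverage), where
  the plain OLS error under-covers.
* **Defaults.** $\tau_0 = 10^{-8}$ s, the conventional lifetime for serum
  albumin, and a diffusion ceiling of $2\times10^{10}$ L mol$^{-1}$
  s$^{-1}$ for the mechanism call; both are overridable arguments.

### Mechanism call

Static quenching (ground-state complex) weakens as temperature rises and
produces apparent $K_q$ far above the diffusion limit; dynamic
(collisional) quenching strengthens with temperature and cannot exceed the
limit. `classify_mechanism()` requires *strict* monotonicity of $K_{sv}$
across all temperatures (ties count as non-monotonic) and a unanimous
$K_q$ comparison; every combination other than the two textbook corners
returns `"ambiguous"`. This is a deliberately conservative evidence
standard: a borderline trend should not produce a confident verdict. The
UV absorbance trend (`absorbance_trend()`) provides advisory corroboration
only — rising absorbance at the aromatic 278 nm band is consistent with
complex formation — and never overrides the fluorescence-based verdict.

## Binding constant and stoichiometry

For static 1:1-type binding the double-logarithmic (modified Stern–Volmer)
relation is fitted:

$$\log_{10}\frac{F_0 - F}{F} = \log_{10} K_b + n \log_{10} [Q]$$

with binding constant $K_b$ (L/mol) as $10^{\text{intercept}}$ and
stoichiometry $n$ as the slope. The $Q=0$ point is necessarily excluded
($\log 0$), as is any point with $F_0 - F \le 0$ (no measurable quenching);
the exclusion count is part of the fit result so that fragile fits are
visible. At small fractional quenching this regression is intrinsically
noise-sensitive — the numerator $F_0 - F$ is a small difference of noisy
quantities — which is why the package reports $R^2$ and standard errors
alongside the estimates.

## Inner filter effect

When the ligand absorbs at the excitation or emission wavelength, observed
intensities are attenuated. The multiplicative correction

$$F_{corr} = F_{obs}\, e^{(A_{ex}+A_{em})/2}$$

is applied pointwise to every titration point *before* any fit whenever
absorbance data are supplied; the fits record whether it was applied. The
correction is optional because published analyses do not always state
whether it was used; leaving it off reproduces the uncorrected arithmetic.

## Van't Hoff thermodynamics

Binding constants at two or more temperatures are regressed as

$$\log_{10} K_b = -\frac{\Delta H^\circ}{\ln(10)\,R\,T} +
  \frac{\Delta S^\circ}{\ln(10)\,R}$$

by OLS of $\log_{10} K_b$ on $1/T$, with $R = 8.314$ J mol$^{-1}$ K$^{-1}$
held fixed (the value as conventionally printed, not CODATA's 8.31446, so
that published arithmetic is reproduced digit-for-digit). The base-10
conversion factor is the exact $\ln(10) = 2.302585\ldots$, of which the
2.303 seen in the literature is a rounding: with the exact factor the two
Gibbs free-energy routes,

$$\Delta G^\circ = \Delta H^\circ - T\Delta S^\circ
  \quad\text{and}\quad
  \Delta G^\circ = -RT\ln K_b,$$

agree to machine precision on any van't-Hoff-consistent input, which the
test suite asserts. With the rounded 2.303 they would disagree by ~0.02%,
an avoidable internal inconsistency. kcal conversions use the
thermochemical calorie (4184 J/kcal), standard in the binding literature.

Dominant binding forces follow the classical sign rules
(`classify_forces()`): $\Delta H^\circ<0,\ \Delta S^\circ<0$ → hydrogen
bonding + van der Waals; both positive → hydrophobic; $\Delta H^\circ<0,\
\Delta S^\circ>0$ → electrostatic; any zero, or
$\Delta H^\circ>0,\ \Delta S^\circ<0$, → indeterminate. This is a pure
sign lookup with no magnitude thresholds.

A caution the package makes no attempt to hide: enthalpies refitted from
*rounded, published* three-temperature binding constants can differ
substantially from the enthalpy printed alongside them (three points in
log space amplify rounding), so `fit_vant_hoff()` output on re-digitized
tables should be read as internally consistent with its own inputs, not as
a recovery of unpublished intermediate precision.

## CD secondary structure

Observed ellipticity (mdeg) converts to molar ellipticity as
$[\theta] = 100\,\theta/(C\,l)$ with $C$ in mol/L and $l$ in cm.
Secondary-structure fractions are estimated by linear unmixing against
four basis spectra (alpha helix, beta, turn, random coil):

$$\min_f \|y - Bf\|_2 \quad \text{s.t.}\quad f_k \ge 0,\ \textstyle\sum_k f_k = 1.$$

* **Solver.** The simplex constraint is handled *exactly*: with four
  components the quadratic program's optimum has some active set, so the
  solver enumerates all 15 non-empty supports, solves each
  equality-constrained problem by substituting $f_m = 1 - \sum_{j\ne m}
  f_j$, discards infeasible candidates, and keeps the best. Fractions are
  feasible by construction, never clipped after the fact; exact admissible
  combinations are recovered to machine precision.
* **Fit window.** 200–260 nm by default: the far-UV structural bands
  (208–222 nm for helix, ~200 nm for coil) lie there, and longer
  wavelengths carry little structural information. At least 20 overlapping
  grid points are required; basis spectra are interpolated onto the
  measured grid.
* **Basis.** The shipped basis (`cd_basis_synthetic()`) is *synthetic*:
  Gaussian lobes at the canonical band positions (helix: negative 209/222
  nm; beta: negative 216, positive 198 nm; turn: positive 205 nm; coil:
  negative 200 nm), with condition number ≈ 29 over the default window.
  Instrument-vendor reference sets are proprietary and cannot ship here;
  the synthetic basis makes the unmixing *mechanics* fully testable, and
  `read_basis_set()` accepts user bases for real data. Consequently,
  fractions obtained on real spectra with the synthetic basis are not
  comparable to vendor-software percentages — only trends are. The beta
  component stays in the basis even when fits drive it to zero.
* **Conditioning.** A basis whose components are near-collinear over the
  window (condition number above $10^6$) attaches a warning to the result
  instead of failing, since the constrained optimum is still well-defined.

## UV and FT-IR band analysis

Buffer/ligand contributions are removed by pointwise difference spectra
(`difference_spectrum()`, anti-symmetric by construction; identical grids
required unless interpolation is requested). Amide band maxima are located
within fixed windows — amide I 1600–1700 cm$^{-1}$; amide II 1500–1580
cm$^{-1}$, a symmetric window around the canonical 1548 cm$^{-1}$ — and
refined to sub-grid precision by a three-point parabola through the grid
maximum, falling back to the grid point when the parabola is degenerate
(flat or non-concave) and warning when the maximum sits on a window edge.
Parabolic refinement (rather than centroiding) was chosen because reported
amide-I positions carry two decimals, implying sub-grid precision; on
analytic bands it is translation-equivariant to within 0.01 cm$^{-1}$.
The free→bound shift is reported as `peak_bound - peak_free`.

## The synthetic-data generator

Every stage is verified by parameter recovery against
generated data with known ground truth, because the study conditions the
package emulates (a 15 µM protein titrated with 0–120 µM ligand at 288,
298 and 308 K, excitation 280 nm, emission read at 344 nm) do not come
with public raw spectra.

* **Generative law.** Peak intensity follows
  $F = F_0/(1 + K_b Q^n)$. This single law makes *both* fitted relations
  exact simultaneously: at $n=1$ the Stern–Volmer plot is a straight line
  with slope $K_{sv} = K_b$, and for any $n$ the double-log plot is exact
  with slope $n$ and intercept $\log_{10} K_b$. Ligand depletion
  (free vs total concentration) is deliberately ignored — the fitted
  equations themselves make the same approximation, so the generator and
  the estimators share one model and recovery is a sharp test of the
  fitting code rather than of model mismatch.
* **Defaults as study conditions.** Gaussian emission lineshape centered
  at 344 nm with 30 nm width; three temperatures (288, 298, 308 K) with
  binding constants 34160, 5200 and 1670 L/mol — a static, exothermic
  binder whose affinity falls with temperature; nine titration points.
* **Noise.** Optional iid Gaussian noise per grid point, parameterized as
  a fraction of the unquenched amplitude; the defaults are *fixture
  choices*, not claims about any instrument. All randomness flows through
  one explicitly seeded generator per call, with the caller's RNG state
  restored afterwards, so identical truth objects give bit-identical
  series.
* **What passing does not show.** The generator draws iid Gaussian noise
  on a shared grid, with no drift, no wavelength-dependent noise, no
  stray-light baseline, no ligand depletion and no lineshape change.
  Recovery under these conditions validates the estimators' arithmetic and
  their statistical calibration, not robustness to every instrument
  artifact of real titrations.

## Orchestration and reproducibility

`run_full_analysis()` runs all stages from one YAML config, skipping
stages whose inputs are absent with a logged notice, recording every
paper-gap decision (analysis wavelength used, IFE applied or not, points
excluded from the double-log fit) in a run log, and writing
fixed-format tables so that report regeneration from identical inputs is
byte-identical. Problem sizes throughout the test suite are small by
design — nine-point titrations on 201-point spectra, 61-point CD grids,
100–200-seed replicate studies — which keeps the whole suite to a few
seconds while leaving the statistical assertions (coverage, unbiasedness)
well-powered.

## Known limitations

* Linear Stern–Volmer only: no upward-curving combined static+dynamic
  model, no lifetime-resolved analysis.
* Van't Hoff is two-parameter (constant $\Delta C_p = 0$); no error
  propagation beyond regression standard errors.
* CD unmixing does not reimplement SELCON/CONTIN/CDSSTR reference-set
  algorithms and does not subdivide beta classes; IR analysis stops at
  peak shifts (no Fourier self-deconvolution of amide sub-bands).
* Proprietary instrument binary formats are out of scope; spectra are
  two-column delimited text.
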