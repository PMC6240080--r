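# Van't Hoff thermodynamics of binding and force classification.
#
# All regressions are in base-10 logarithms; the conversion factor is the
# exact ln(10), of which the conventional 2.303 is the printed rounding.
# The gas constant is fixed at 8.314 J mol^-1 K^-1.

#' Van't Hoff regression of binding constants
#'
#' Fits `log10 Kb = -dH/(ln(10) R T) + dS/(ln(10) R)` by ordinary least
#' squares of log10(Kb) on 1/T: `dH = -ln(10) R slope`,
#' `dS = ln(10) R intercept`. The Gibbs free energy is populated at every
#' input temperature via `dG = dH - T dS`, and the dominant binding force is
#' classified from the signs of dH and dS (see [classify_forces()]).
#'
#' @param temperature temperatures, K (>= 2, distinct).
#' @param Kb binding constants, L/mol (> 0), same length.
#' @return object of class `thermo_params` with fields `dH` (J/mol), `dS`
#'   (J/(mol K)), `dG_at` (named numeric, J/mol, by temperature),
#'   `r_squared`, `force_class`, `gas_constant`.
#' @examples
#' fit_vant_hoff(c(288, 298, 308), c(34160, 5200, 1670))
#' @export
fit_vant_hoff <- function(temperature, Kb) {
  if (length(temperature) != length(Kb) || length(Kb) < 2L) {
    abort_sb("need >= 2 (temperature, Kb) pairs", "specbind_insufficient_data")
  }
  if (any(Kb <= 0)) abort_sb("all Kb must be > 0", "specbind_invalid_input")
  if (any(temperature <= 0)) abort_sb("temperatures must be > 0 K",
                                      "specbind_invalid_input")
  if (anyDuplicated(temperature)) abort_sb("duplicate temperatures",
                                           "specbind_invalid_input")
  x <- 1 / temperature
  y <- log10(Kb)
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  dH <- -log(10) * GAS_CONSTANT * unname(co[2])
  dS <- log(10) * GAS_CONSTANT * unname(co[1])
  r2 <- if (length(Kb) > 2L) suppressWarnings(summary(fit))$r.squared else 1
  Ts <- sort(temperature)
  dG <- dH - Ts * dS
  names(dG) <- as.character(Ts)
  structure(
    list(dH = dH, dS = dS, dG_at = dG, r_squared = r2,
         force_class = classify_forces(dH, dS), gas_constant = GAS_CONSTANT),
    class = "thermo_params"
  )
}

#' @export
print.thermo_params <- function(x, ...) {
  cat(sprintf("<thermo_params: dH = %.2f kJ/mol, dS = %.2f J/(mol K), forces: %s>\n",
              x$dH / 1000, x$dS, x$force_class))
  for (Tk in names(x$dG_at)) {
    cat(sprintf("  dG(%s K) = %.2f kJ/mol%s\n", Tk, x$dG_at[[Tk]] / 1000,
                if (x$dG_at[[Tk]] < 0) " (spontaneous)" else ""))
  }
  invisible(x)
}

#' Gibbs free energy from enthalpy and entropy
#'
#' `dG = dH - T dS`, exact arithmetic.
#'
#' @param dH enthalpy change, J/mol.
#' @param dS entropy change, J/(mol K).
#' @param temperature temperature, K (> 0); vectorized.
#' @return Gibbs free energy change, J/mol.
#' @examples
#' gibbs_from_enthalpy_entropy(-128470, -359.49, 298) / 1000  # kJ/mol
#' @export
gibbs_from_enthalpy_entropy <- function(dH, dS, temperature) {
  if (any(temperature <= 0)) abort_sb("temperature must be > 0",
                                      "specbind_invalid_input")
  dH - temperature * dS
}

#' Gibbs free energy from a binding constant
#'
#' `dG = -R T ln(Kb)` with R = 8.314 J/(mol K). Use [joules_to_kcal()] for
#' the kcal/mol scale common in docking work.
#'
#' @param Kb binding constant, L/mol (> 0); vectorized.
#' @param temperature temperature, K (> 0).
#' @return Gibbs free energy change, J/mol.
#' @examples
#' joules_to_kcal(gibbs_from_kb(5.20e3, 298))  # about -5.1 kcal/mol
#' @export
gibbs_from_kb <- function(Kb, temperature) {
  if (any(Kb <= 0)) abort_sb("Kb must be > 0", "specbind_invalid_input")
  if (any(temperature <= 0)) abort_sb("temperature must be > 0",
                                      "specbind_invalid_input")
  -GAS_CONSTANT * temperature * log(Kb)
}

#' Dominant binding force from thermodynamic signs
#'
#' The classical sign rules for protein-ligand binding: dH < 0 and dS < 0
#' indicate hydrogen bonding and van der Waals contacts; dH > 0 and dS > 0
#' indicate hydrophobic interactions; dH < 0 with dS > 0 indicates
#' electrostatic forces. A zero in either quantity, or dH > 0 with dS < 0,
#' is indeterminate. Pure sign lookup, no thresholds.
#'
#' @param dH enthalpy change, J/mol.
#' @param dS entropy change, J/(mol K).
#' @return one of `"hbond_vdw"`, `"hydrophobic"`, `"electrostatic"`,
#'   `"indeterminate"`.
#' @export
classify_forces <- function(dH, dS) {
  if (dH < 0 && dS < 0) "hbond_vdw"
  else if (dH > 0 && dS > 0) "hydrophobic"
  else if (dH < 0 && dS > 0) "electrostatic"
  else "indeterminate"
}
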