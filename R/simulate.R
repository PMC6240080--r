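# Synthetic titrations, CD, UV and IR spectra with known ground truth.
#
# The generative quenching law is F = F0 / (1 + Kb * Q^n): with n = 1 the
# Stern-Volmer relation F0/F = 1 + Ksv*[Q] holds exactly with Ksv = Kb, and
# for any n the double-log relation log10((F0-F)/F) = log10 Kb + n log10 [Q]
# holds exactly, so both downstream fits can be checked by parameter
# recovery. Free-vs-total ligand depletion is deliberately ignored, matching
# the fitted equations themselves.

GAS_CONSTANT <- 8.314  # J mol^-1 K^-1, fixed

#' Ground truth for a simulated quenching titration
#'
#' @param Kb_per_T named numeric vector mapping temperature (K, as names) to
#'   binding constant Kb (L/mol). Defaults to the three-temperature design
#'   used throughout the package: 34160, 5200 and 1670 L/mol at 288, 298 and
#'   308 K, a static quencher whose affinity falls with temperature.
#' @param n binding stoichiometry (dimensionless, > 0).
#' @param F0_amplitude unquenched peak intensity, arbitrary units.
#' @param emission_center emission maximum, nm.
#' @param emission_width Gaussian width (standard deviation) of the emission
#'   lineshape, nm.
#' @param noise_sd per-point Gaussian noise, as a fraction of `F0_amplitude`.
#' @param seed integer seed; identical truth (including seed) gives
#'   bit-identical simulations.
#' @return object of class `quenching_ground_truth`.
#' @export
quenching_ground_truth <- function(Kb_per_T = c("288" = 34160, "298" = 5200,
                                                "308" = 1670),
                                   n = 1, F0_amplitude = 1000,
                                   emission_center = 344, emission_width = 30,
                                   noise_sd = 0, seed = 1L) {
  if (any(Kb_per_T <= 0)) abort_sb("all Kb must be > 0", "specbind_invalid_input")
  if (is.null(names(Kb_per_T)) || anyNA(suppressWarnings(as.numeric(names(Kb_per_T))))) {
    abort_sb("Kb_per_T must be named by temperature in K", "specbind_invalid_input")
  }
  if (!is_number(n) || n <= 0) abort_sb("n must be > 0", "specbind_invalid_input")
  if (!is_number(emission_width) || emission_width <= 0) {
    abort_sb("emission_width must be > 0", "specbind_invalid_input")
  }
  if (!is_number(noise_sd) || noise_sd < 0) {
    abort_sb("noise_sd must be >= 0", "specbind_invalid_input")
  }
  structure(
    list(Kb_per_T = Kb_per_T, n = n, F0_amplitude = F0_amplitude,
         emission_center = emission_center, emission_width = emission_width,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "quenching_ground_truth"
  )
}

#' Simulate a fluorescence quenching titration
#'
#' Emits a titration series whose noiseless peak intensity obeys
#' `F = F0 / (1 + Kb * Q^n)` exactly at each quencher concentration. Each
#' spectrum is a Gaussian lineshape centered at the truth's emission center
#' (the peak shape and position do not change with quenching, as observed for
#' serum albumin). When `noise_sd > 0`, iid Gaussian noise with standard
#' deviation `noise_sd * F0_amplitude` is added at every grid point.
#'
#' @param truth a [quenching_ground_truth()].
#' @param temperature temperature in K; must be one of the truth's
#'   `Kb_per_T` temperatures.
#' @param quencher_concs quencher concentrations in mol/L, starting at 0,
#'   strictly increasing. Default 0 to 120 uM in 15 uM steps.
#' @param axis emission wavelength grid, nm.
#' @param protein_conc protein concentration, mol/L.
#' @param excitation_wavelength excitation wavelength, nm.
#' @return a `titration_series` of emission spectra.
#' @export
simulate_quenching_titration <- function(truth, temperature,
                                         quencher_concs = seq(0, 120e-6, by = 15e-6),
                                         axis = seq(300, 500, by = 1),
                                         protein_conc = 15e-6,
                                         excitation_wavelength = 280) {
  stopifnot(inherits(truth, "quenching_ground_truth"))
  if (quencher_concs[1] != 0 || any(diff(quencher_concs) <= 0)) {
    abort_sb("quencher_concs must start at 0 and be strictly increasing",
             "specbind_ordering_error")
  }
  key <- match(as.character(temperature), names(truth$Kb_per_T))
  if (is.na(key)) {
    abort_sb(sprintf("no ground-truth Kb at %g K", temperature),
             "specbind_invalid_input")
  }
  Kb <- unname(truth$Kb_per_T[key])
  lineshape <- exp(-0.5 * ((axis - truth$emission_center) / truth$emission_width)^2)
  noise_abs <- truth$noise_sd * truth$F0_amplitude
  points <- with_seed(truth$seed + key, {
    lapply(quencher_concs, function(q) {
      f_peak <- truth$F0_amplitude / (1 + Kb * q^truth$n)
      sig <- f_peak * lineshape
      if (noise_abs > 0) sig <- sig + stats::rnorm(length(sig), 0, noise_abs)
      list(quencher_conc = q, spectrum = spectrum(axis, sig, "emission"))
    })
  })
  titration_series(protein_conc, temperature, points,
                   excitation_wavelength = excitation_wavelength)
}

#' Binding constant from van't Hoff parameters
#'
#' Evaluates the integrated van't Hoff relation
#' `log10 Kb = -dH/(ln(10) R T) + dS/(ln(10) R)` with R = 8.314 J/(mol K).
#' Equivalently `Kb = exp(-(dH - T dS)/(R T))`, so constants generated here
#' are exactly consistent with both Gibbs free-energy routes.
#'
#' @param dH standard enthalpy change, J/mol.
#' @param dS standard entropy change, J/(mol K).
#' @param temperature temperature(s), K (> 0); vectorized.
#' @return binding constant(s), L/mol.
#' @examples
#' kb_from_vant_hoff(0, 0, 298)          # 1 at any T
#' kb_from_vant_hoff(-1e5, -300, 298)
#' @export
kb_from_vant_hoff <- function(dH, dS, temperature) {
  if (any(temperature <= 0)) abort_sb("temperature must be > 0",
                                      "specbind_invalid_input")
  exp(-(dH - temperature * dS) / (GAS_CONSTANT * temperature))
}

#' Simulate a circular dichroism spectrum from structure fractions
#'
#' The signal is the linear combination `sum_k fraction_k * basis_k` over the
#' basis grid, plus optional iid Gaussian noise in mdeg.
#'
#' @param fractions numeric vector of 4 non-negative fractions
#'   (alpha_helix, beta, turn, random) summing to 1 within 1e-9.
#' @param basis a [basis_set()].
#' @param noise_sd noise standard deviation, mdeg.
#' @param seed integer seed.
#' @return a `spectrum` of kind `cd_ellipticity_mdeg`.
#' @export
simulate_cd_spectrum <- function(fractions, basis, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(basis, "basis_set"))
  fractions <- as.numeric(fractions)
  if (length(fractions) != 4L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    abort_sb("fractions must be 4 non-negative values summing to 1",
             "specbind_invalid_composition")
  }
  sig <- as.numeric(basis$components %*% fractions)
  if (noise_sd > 0) {
    sig <- with_seed(seed, sig + stats::rnorm(length(sig), 0, noise_sd))
  }
  spectrum(basis$axis, sig, "cd_ellipticity_mdeg")
}

#' Simulate a single-band spectrum
#'
#' A Lorentzian band `amplitude / (1 + ((x - center)/width)^2)` on the given
#' grid, plus optional Gaussian noise. Used as an analytic fixture for peak
#' finding; the peak of the noiseless curve lies at the grid point nearest
#' the center.
#'
#' @param center band center, axis units.
#' @param width half-width at half-maximum, axis units (> 0).
#' @param amplitude peak amplitude.
#' @param axis axis grid.
#' @param noise_sd noise standard deviation (signal units).
#' @param seed integer seed.
#' @param kind spectrum kind tag; default `"ir_absorbance"`.
#' @return a `spectrum`.
#' @export
simulate_band_spectrum <- function(center, width, amplitude,
                                   axis = seq(1000, 1900, by = 1),
                                   noise_sd = 0, seed = 1L,
                                   kind = "ir_absorbance") {
  if (!is_number(width) || width <= 0) abort_sb("width must be > 0",
                                                "specbind_invalid_input")
  sig <- amplitude / (1 + ((axis - center) / width)^2)
  if (noise_sd > 0) {
    sig <- with_seed(seed, sig + stats::rnorm(length(sig), 0, noise_sd))
  }
  spectrum(axis, sig, kind)
}

#' Write a complete synthetic study bundle to disk
#'
#' Generates one quenching titration manifest (plus spectrum files) per
#' ground-truth temperature, in the package's plain-text formats, together
#' with a `truth.yml` recording every generative parameter. This is the
#' fixture used for end-to-end recovery tests and for demonstrating
#' [run_full_analysis()].
#'
#' @param dir output directory (created if absent).
#' @param truth a [quenching_ground_truth()].
#' @param quencher_concs quencher grid, mol/L.
#' @return invisibly, a list with `manifests` (paths, named by temperature)
#'   and `truth`.
#' @export
simulate_study_bundle <- function(dir, truth = quenching_ground_truth(),
                                  quencher_concs = seq(0, 120e-6, by = 15e-6)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  temps <- as.numeric(names(truth$Kb_per_T))
  manifests <- character(0)
  for (Tk in temps) {
    series <- simulate_quenching_titration(truth, Tk, quencher_concs)
    mdir <- file.path(dir, sprintf("T%03d", round(Tk)))
    dir.create(mdir, showWarnings = FALSE)
    pts <- list()
    for (i in seq_along(series$points)) {
      fname <- sprintf("em_%02d.csv", i)
      write_spectrum(series$points[[i]]$spectrum, file.path(mdir, fname))
      pts[[i]] <- list(quencher_conc_uM = series$points[[i]]$quencher_conc * 1e6,
                       file = fname)
    }
    mpath <- file.path(mdir, "manifest.yml")
    yaml::write_yaml(list(
      protein_conc_uM = series$protein_conc * 1e6,
      temperature_K = Tk,
      excitation_nm = series$excitation_wavelength,
      kind = "emission",
      points = pts
    ), mpath)
    manifests[as.character(Tk)] <- mpath
  }
  yaml::write_yaml(list(
    Kb_per_T = as.list(truth$Kb_per_T), n = truth$n,
    F0_amplitude = truth$F0_amplitude,
    emission_center = truth$emission_center,
    emission_width = truth$emission_width,
    noise_sd = truth$noise_sd, seed = truth$seed
  ), file.path(dir, "truth.yml"))
  invisible(list(manifests = manifests, truth = truth))
}
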