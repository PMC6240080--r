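# Fluorescence quenching analysis: inner-filter correction, Stern-Volmer and
# double-log regressions, bimolecular rate constant, mechanism call.

#' Inner filter effect correction
#'
#' Corrects observed fluorescence for attenuation of the excitation and
#' emission beams by sample absorbance:
#' `F_corr = F_obs * exp((A_ex + A_em) / 2)`.
#'
#' @param F_obs observed intensity (vectorized).
#' @param A_ex absorbance at the excitation wavelength (>= 0).
#' @param A_em absorbance at the emission wavelength (>= 0).
#' @return corrected intensity; always >= `F_obs`, with equality iff both
#'   absorbances are zero.
#' @examples
#' correct_inner_filter(100, 0.1, 0.1)  # 100 * exp(0.1)
#' @export
correct_inner_filter <- function(F_obs, A_ex, A_em) {
  if (any(A_ex < 0) || any(A_em < 0)) {
    abort_sb("absorbances must be >= 0", "specbind_invalid_input")
  }
  F_obs * exp((A_ex + A_em) / 2)
}

# Shared front end for the two quenching fits: read F at the analysis
# wavelength (default: emission max of the quencher-free spectrum), apply
# the IFE correction when absorbances are supplied.
quenching_intensities <- function(series, wavelength = NULL,
                                  A_ex = NULL, A_em = NULL) {
  stopifnot(inherits(series, "titration_series"))
  if (is.null(wavelength)) wavelength <- emission_max(series)
  tab <- extract_intensity(series, wavelength)
  ife_applied <- FALSE
  if (!is.null(A_ex) || !is.null(A_em)) {
    if (is.null(A_ex)) A_ex <- 0
    if (is.null(A_em)) A_em <- 0
    npt <- nrow(tab)
    A_ex <- rep_len(A_ex, npt)
    A_em <- rep_len(A_em, npt)
    tab$signal <- correct_inner_filter(tab$signal, A_ex, A_em)
    ife_applied <- TRUE
  }
  list(tab = tab, wavelength = wavelength, ife_applied = ife_applied)
}

#' Stern-Volmer regression
#'
#' Fits `F0/F = 1 + Ksv * [Q]` by ordinary least squares of F0/F on the
#' quencher concentration, over all points including Q = 0, with a free
#' intercept. An intercept deviating from 1 by more than 0.05 flags model
#' misfit and is recorded on the result. The bimolecular quenching rate
#' constant is `Kq = Ksv / tau0`.
#'
#' @param series a `titration_series` of emission spectra.
#' @param tau0 unquenched fluorophore lifetime, s; default 1e-8 s, the value
#'   conventionally assumed for serum albumin.
#' @param wavelength analysis wavelength, nm; default the emission maximum of
#'   the quencher-free spectrum.
#' @param A_ex,A_em optional per-point absorbances for inner-filter
#'   correction, applied before the fit.
#' @return object of class `quenching_fit` with fields `Ksv` (L/mol),
#'   `Ksv_se`, `intercept`, `r_squared`, `tau0`, `Kq` (L mol^-1 s^-1),
#'   `temperature`, `wavelength`, `ife_applied`, `intercept_warning`.
#' @export
fit_stern_volmer <- function(series, tau0 = 1e-8, wavelength = NULL,
                             A_ex = NULL, A_em = NULL) {
  if (!is_number(tau0) || tau0 <= 0) abort_sb("tau0 must be > 0",
                                              "specbind_invalid_input")
  qi <- quenching_intensities(series, wavelength, A_ex, A_em)
  tab <- qi$tab
  if (any(tab$signal <= 0)) {
    abort_sb("non-positive fluorescence at the analysis wavelength",
             "specbind_degenerate_signal")
  }
  if (nrow(tab) < 3L) abort_sb("need at least 3 points",
                               "specbind_insufficient_data")
  F0 <- tab$signal[1]
  y <- F0 / tab$signal
  x <- tab$quencher_conc
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # exact fits trigger a benign warning
  co <- sm$coefficients
  ksv <- unname(co[2, 1])
  r2 <- sm$r.squared
  icpt <- unname(co[1, 1])
  # Slope SE: F0/F ratios are heteroscedastic (noise grows ~ y^2) and all
  # points share the one measured F0, so the plain OLS SE is too small. Use
  # the HC3 sandwich plus propagation of the common-mode F0 term, whose
  # relative sd is estimated from the leverage-adjusted residuals.
  X <- cbind(1, x)
  h <- pmin(stats::hat(X), 1 - 1e-8)
  r_adj <- stats::resid(fit) / (1 - h)
  XtXi <- solve(crossprod(X))
  V <- XtXi %*% crossprod(X * r_adj) %*% XtXi
  i <- which(x > 0)
  s0rel <- sqrt(mean(r_adj[i]^2) / mean(y[i]^4))
  ksv_se <- sqrt(V[2, 2] + ksv^2 * s0rel^2)
  structure(
    list(Ksv = ksv, Ksv_se = ksv_se, intercept = icpt,
         r_squared = r2, tau0 = tau0, Kq = ksv / tau0,
         temperature = series$temperature, wavelength = qi$wavelength,
         ife_applied = qi$ife_applied,
         intercept_warning = abs(icpt - 1) > 0.05,
         data = data.frame(quencher_conc = tab$quencher_conc, F0_over_F = y)),
    class = "quenching_fit"
  )
}

#' @export
print.quenching_fit <- function(x, ...) {
  cat(sprintf("<quenching_fit @ %g K: Ksv = %.4g +/- %.2g L/mol, Kq = %.4g /M/s, R^2 = %.4f>\n",
              x$temperature, x$Ksv, x$Ksv_se, x$Kq, x$r_squared))
  if (isTRUE(x$intercept_warning)) {
    cat(sprintf("  note: intercept %.3f deviates from 1 by > 0.05\n", x$intercept))
  }
  invisible(x)
}

#' Double-log (modified Stern-Volmer) binding fit
#'
#' Fits `log10((F0 - F)/F) = log10 Kb + n log10 [Q]` by ordinary least
#' squares. The quencher-free point (log 0 undefined) and any point with
#' `F0 - F <= 0` are excluded; the exclusion count is reported.
#'
#' @inheritParams fit_stern_volmer
#' @return object of class `binding_fit` with fields `Kb` (L/mol), `n`,
#'   `log10_Kb_se`, `n_se`, `r_squared`, `temperature`, `points_used`,
#'   `points_excluded`.
#' @export
fit_binding <- function(series, wavelength = NULL, A_ex = NULL, A_em = NULL) {
  qi <- quenching_intensities(series, wavelength, A_ex, A_em)
  tab <- qi$tab
  F0 <- tab$signal[1]
  usable <- tab$quencher_conc > 0 & (F0 - tab$signal) > 0 & tab$signal > 0
  excluded <- sum(!usable)
  if (sum(usable) < 2L) {
    abort_sb(sprintf("only %d usable points after excluding %d",
                     sum(usable), excluded),
             "specbind_insufficient_data")
  }
  x <- log10(tab$quencher_conc[usable])
  y <- log10((F0 - tab$signal[usable]) / tab$signal[usable])
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  structure(
    list(Kb = 10^unname(co[1, 1]), n = unname(co[2, 1]),
         log10_Kb_se = unname(co[1, 2]), n_se = unname(co[2, 2]),
         r_squared = sm$r.squared,
         temperature = series$temperature,
         points_used = sum(usable), points_excluded = excluded,
         wavelength = qi$wavelength, ife_applied = qi$ife_applied),
    class = "binding_fit"
  )
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("<binding_fit @ %g K: Kb = %.4g L/mol, n = %.4f, R^2 = %.4f (%d points, %d excluded)>\n",
              x$temperature, x$Kb, x$n, x$r_squared,
              x$points_used, x$points_excluded))
  invisible(x)
}

#' Static vs dynamic quenching mechanism call
#'
#' Static quenching (ground-state complex) weakens with temperature and shows
#' apparent bimolecular rate constants far above the diffusion limit;
#' collisional (dynamic) quenching strengthens with temperature and stays at
#' or below the limit. The verdict is `"static"` only when Ksv decreases
#' strictly with temperature AND every Kq exceeds the diffusion limit;
#' `"dynamic"` only when Ksv increases strictly AND no Kq exceeds it; any
#' other combination is `"ambiguous"`. Ties count as non-monotonic.
#'
#' @param fits list of `quenching_fit` objects at distinct temperatures
#'   (>= 2).
#' @param diffusion_limit maximum diffusion-limited rate constant,
#'   L mol^-1 s^-1; default 2e10, the usual biomolecule ceiling.
#' @return object of class `mechanism_call` with fields `verdict`,
#'   `ksv_trend`, `kq_exceeds_diffusion_limit`, `evidence`.
#' @export
classify_mechanism <- function(fits, diffusion_limit = 2e10) {
  if (length(fits) < 2L) abort_sb("need fits at >= 2 temperatures",
                                  "specbind_insufficient_data")
  temps <- vapply(fits, function(f) f$temperature, numeric(1))
  if (anyDuplicated(temps)) abort_sb("duplicate temperatures",
                                     "specbind_invalid_input")
  ord <- order(temps)
  temps <- temps[ord]
  ksv <- vapply(fits, function(f) f$Ksv, numeric(1))[ord]
  kq <- vapply(fits, function(f) f$Kq, numeric(1))[ord]
  d <- diff(ksv)
  ksv_trend <- if (all(d < 0)) "decreasing" else if (all(d > 0)) "increasing"
               else "non-monotonic"
  kq_exceeds <- all(kq > diffusion_limit)
  verdict <- if (ksv_trend == "decreasing" && kq_exceeds) "static"
             else if (ksv_trend == "increasing" && !kq_exceeds) "dynamic"
             else "ambiguous"
  evidence <- c(
    sprintf("Ksv: %s across %s K -> %s trend",
            paste(sprintf("%.4g", ksv), collapse = ", "),
            paste(temps, collapse = ", "), ksv_trend),
    sprintf("Kq %s vs %.4g: %s diffusion limit",
            paste(sprintf("%.4g", kq), collapse = ", "), diffusion_limit,
            if (kq_exceeds) "all exceed the" else "not all exceed the"))
  structure(
    list(verdict = verdict, ksv_trend = ksv_trend,
         kq_exceeds_diffusion_limit = kq_exceeds,
         diffusion_limit = diffusion_limit, evidence = evidence),
    class = "mechanism_call"
  )
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat(sprintf("<mechanism_call: %s>\n", x$verdict))
  for (e in x$evidence) cat(" ", e, "\n")
  invisible(x)
}
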