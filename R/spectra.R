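# Spectrum and titration-series containers plus plain-text readers/writers.
#
# Conventions: the axis is always stored strictly ascending (IR traces
# conventionally plotted in descending wavenumber are re-sorted on load);
# concentrations are carried in mol/L internally, manifests declare uM.

SPECTRUM_KINDS <- c("emission", "absorbance", "cd_ellipticity_mdeg", "ir_absorbance")

#' Construct a spectrum
#'
#' A spectrum is one recorded trace: an ordered axis (wavelength in nm for
#' emission/absorbance/CD, wavenumber in cm^-1 for IR) with a signal value at
#' each axis point and a kind tag. The axis is normalized to strictly
#' ascending order; duplicated axis values are rejected.
#'
#' @param axis numeric axis positions (nm or cm^-1 depending on `kind`).
#' @param signal numeric signal values, same length as `axis`.
#' @param kind one of `"emission"`, `"absorbance"`, `"cd_ellipticity_mdeg"`,
#'   `"ir_absorbance"`.
#' @return an object of class `spectrum` with fields `axis`, `signal`, `kind`.
#' @examples
#' s <- spectrum(c(300, 344, 500), c(0, 100, 0), "emission")
#' s$axis
#' @export
spectrum <- function(axis, signal, kind) {
  kind <- match.arg(kind, SPECTRUM_KINDS)
  if (!is.numeric(axis) || !is.numeric(signal)) {
    abort_sb("axis and signal must be numeric", "specbind_invalid_input")
  }
  if (length(axis) != length(signal)) {
    abort_sb(sprintf("axis (%d) and signal (%d) lengths differ",
                     length(axis), length(signal)),
             "specbind_invalid_input")
  }
  if (length(axis) < 3L) {
    abort_sb("a spectrum needs at least 3 points", "specbind_insufficient_data")
  }
  if (anyNA(axis) || any(!is.finite(axis))) {
    abort_sb("axis contains non-finite values", "specbind_invalid_input")
  }
  if (anyNA(signal) || any(!is.finite(signal))) {
    abort_sb("signal contains non-finite values", "specbind_invalid_input")
  }
  if (anyDuplicated(axis)) {
    abort_sb("duplicated axis values are not allowed", "specbind_invalid_input")
  }
  ord <- order(axis)
  structure(
    list(axis = as.numeric(axis[ord]), signal = as.numeric(signal[ord]),
         kind = kind),
    class = "spectrum"
  )
}

#' @export
print.spectrum <- function(x, ...) {
  unit <- if (x$kind == "ir_absorbance") "cm^-1" else "nm"
  cat(sprintf("<spectrum: %s, %d points, axis %.6g-%.6g %s>\n",
              x$kind, length(x$axis), min(x$axis), max(x$axis), unit))
  invisible(x)
}

#' Read a spectrum from two-column delimited text
#'
#' Accepts comma- or whitespace-delimited rows of (axis, signal); lines
#' starting with `#` are comments. Rows may appear in any axis order; the
#' result is sorted ascending.
#'
#' @param path file path.
#' @param kind spectrum kind, see [spectrum()].
#' @return a `spectrum`.
#' @export
read_spectrum <- function(path, kind) {
  if (!file.exists(path)) {
    abort_sb(sprintf("spectrum file not found: %s", path), "specbind_missing_file")
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  axis <- numeric(0)
  signal <- numeric(0)
  for (i in rows) {
    fields <- strsplit(trimws(lines[i]), "[,[:space:]]+")[[1]]
    fields <- fields[nzchar(fields)]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) != 2L || anyNA(vals)) {
      abort_sb(sprintf("parse error in %s at line %d: %s", path, i, lines[i]),
               "specbind_parse_error")
    }
    axis <- c(axis, vals[1])
    signal <- c(signal, vals[2])
  }
  if (length(axis) < 3L) {
    abort_sb(sprintf("%s: fewer than 3 data points", path),
             "specbind_insufficient_data")
  }
  spectrum(axis, signal, kind)
}

#' Write a spectrum as two-column delimited text
#'
#' Full double precision is preserved so that write/read round-trips exactly.
#'
#' @param x a `spectrum`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(x, path) {
  stopifnot(inherits(x, "spectrum"))
  header <- sprintf("# specbind spectrum kind=%s", x$kind)
  body <- sprintf("%.17g,%.17g", x$axis, x$signal)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Construct a titration series
#'
#' One protein solution at one temperature, observed at increasing quencher
#' (ligand) concentrations. The first point must be quencher-free: it defines
#' the reference intensity F0. All spectra must share kind and axis grid.
#'
#' @param protein_conc protein concentration, mol/L (> 0).
#' @param temperature temperature, K (> 0).
#' @param points list of points, each `list(quencher_conc = <mol/L>,
#'   spectrum = <spectrum>)`, ordered by strictly increasing concentration.
#' @param excitation_wavelength excitation wavelength in nm (fluorescence
#'   kinds); `NA` otherwise.
#' @return an object of class `titration_series`.
#' @export
titration_series <- function(protein_conc, temperature, points,
                             excitation_wavelength = NA_real_) {
  if (!is_number(protein_conc) || protein_conc <= 0) {
    abort_sb("protein_conc must be a positive number (mol/L)",
             "specbind_invalid_input")
  }
  if (!is_number(temperature) || temperature <= 0) {
    abort_sb("temperature must be a positive number (K)",
             "specbind_invalid_input")
  }
  if (!is.list(points) || length(points) < 1L) {
    abort_sb("a titration series needs points", "specbind_insufficient_data")
  }
  conc <- vapply(points, function(p) p$quencher_conc, numeric(1))
  if (anyNA(conc) || any(conc < 0)) {
    abort_sb("quencher concentrations must be >= 0", "specbind_invalid_input")
  }
  # F0 and ordering are diagnosed before the point count so that a manifest
  # whose first concentration is nonzero gets the specific error
  if (conc[1] != 0) {
    abort_sb("first titration point must be quencher-free (defines F0)",
             "specbind_missing_f0")
  }
  if (any(diff(conc) <= 0)) {
    abort_sb("quencher concentrations must be strictly increasing",
             "specbind_ordering_error")
  }
  if (length(points) < 3L) {
    abort_sb("a titration series needs at least 3 points",
             "specbind_insufficient_data")
  }
  specs <- lapply(points, function(p) p$spectrum)
  ok <- vapply(specs, inherits, logical(1), what = "spectrum")
  if (!all(ok)) abort_sb("every point needs a spectrum", "specbind_invalid_input")
  kinds <- vapply(specs, function(s) s$kind, character(1))
  if (length(unique(kinds)) != 1L) {
    abort_sb("all spectra in a series must share one kind",
             "specbind_invalid_input")
  }
  ax0 <- specs[[1]]$axis
  same <- vapply(specs, function(s) {
    length(s$axis) == length(ax0) && all(s$axis == ax0)
  }, logical(1))
  if (!all(same)) {
    abort_sb("all spectra in a series must share an identical axis grid",
             "specbind_incompatible_grid")
  }
  structure(
    list(protein_conc = protein_conc, temperature = temperature,
         excitation_wavelength = excitation_wavelength, points = points),
    class = "titration_series"
  )
}

#' @export
print.titration_series <- function(x, ...) {
  conc <- quencher_concentrations(x)
  cat(sprintf(
    "<titration_series: %d points, T = %g K, [P] = %.3g M, [Q] = %.3g-%.3g M, kind %s>\n",
    length(x$points), x$temperature, x$protein_conc,
    min(conc), max(conc), x$points[[1]]$spectrum$kind))
  invisible(x)
}

#' Quencher concentrations of a series
#' @param series a `titration_series`.
#' @return numeric vector, mol/L.
#' @export
quencher_concentrations <- function(series) {
  vapply(series$points, function(p) p$quencher_conc, numeric(1))
}

#' Read a titration manifest
#'
#' The manifest is a YAML file with keys `protein_conc_uM`, `temperature_K`,
#' `excitation_nm` (optional), `kind` (optional, default `"emission"`) and
#' `points`, an ordered list of `{quencher_conc_uM, file}` entries. Spectrum
#' file paths are resolved relative to the manifest's directory.
#' Concentrations are converted from uM to mol/L on load.
#'
#' @param path manifest file path.
#' @return a `titration_series`.
#' @export
read_titration_manifest <- function(path) {
  if (!file.exists(path)) {
    abort_sb(sprintf("manifest not found: %s", path), "specbind_missing_file")
  }
  m <- yaml::read_yaml(path)
  for (key in c("protein_conc_uM", "temperature_K", "points")) {
    if (is.null(m[[key]])) {
      abort_sb(sprintf("manifest %s: missing key '%s'", path, key),
               "specbind_parse_error")
    }
  }
  kind <- if (is.null(m$kind)) "emission" else m$kind
  base <- dirname(path)
  points <- lapply(m$points, function(p) {
    if (is.null(p$quencher_conc_uM) || is.null(p$file)) {
      abort_sb(sprintf("manifest %s: each point needs quencher_conc_uM and file",
                       path), "specbind_parse_error")
    }
    f <- p$file
    if (!grepl("^/", f)) f <- file.path(base, f)
    list(quencher_conc = p$quencher_conc_uM * 1e-6,
         spectrum = read_spectrum(f, kind))
  })
  titration_series(
    protein_conc = m$protein_conc_uM * 1e-6,
    temperature = m$temperature_K,
    excitation_wavelength = if (is.null(m$excitation_nm)) NA_real_ else m$excitation_nm,
    points = points
  )
}

#' Signal at one axis position across a titration
#'
#' Reads the signal at `wavelength` from every spectrum in the series, by
#' linear interpolation between the bracketing grid points; an exact grid hit
#' returns the stored value.
#'
#' @param series a `titration_series`.
#' @param wavelength axis position (nm, or cm^-1 for IR series).
#' @return a `data.frame` with columns `quencher_conc` (mol/L) and `signal`.
#' @export
extract_intensity <- function(series, wavelength) {
  stopifnot(inherits(series, "titration_series"))
  ax <- series$points[[1]]$spectrum$axis
  if (!is_number(wavelength) || wavelength < min(ax) || wavelength > max(ax)) {
    abort_sb(sprintf("wavelength %g outside axis range [%g, %g]",
                     wavelength, min(ax), max(ax)),
             "specbind_out_of_range")
  }
  sig <- vapply(series$points, function(p) {
    stats::approx(p$spectrum$axis, p$spectrum$signal, xout = wavelength,
                  method = "linear", ties = "ordered")$y
  }, numeric(1))
  data.frame(quencher_conc = quencher_concentrations(series), signal = sig)
}

#' Emission maximum of the quencher-free spectrum
#'
#' The default analysis wavelength for quenching fits: the axis position of
#' the maximum signal of the first (quencher-free) spectrum.
#'
#' @param series a `titration_series`.
#' @return axis position of the F0 maximum.
#' @export
emission_max <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  s0 <- series$points[[1]]$spectrum
  s0$axis[which.max(s0$signal)]
}
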