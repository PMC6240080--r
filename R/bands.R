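# UV absorbance trend and FT-IR amide-band peak-shift analysis.

#' Default amide-band windows (cm^-1)
#'
#' Amide I spans 1600-1700 cm^-1; amide II is centered around 1548 cm^-1 and
#' a symmetric 1500-1580 cm^-1 window is adopted for it.
#'
#' @format named list of `c(low, high)` windows.
#' @export
amide_windows <- list(amide_I = c(1600, 1700), amide_II = c(1500, 1580))

#' Difference spectrum
#'
#' Pointwise `sample - reference` (e.g. digital subtraction of the buffer
#' trace from a protein solution trace). Grids must be identical unless
#' `interpolate = TRUE`, in which case the reference is linearly interpolated
#' onto the sample grid over the overlapping range.
#'
#' @param sample a `spectrum`.
#' @param reference a `spectrum` of the same kind.
#' @param interpolate allow interpolation of the reference onto the sample
#'   grid.
#' @return a `spectrum`, kind preserved from `sample`.
#' @export
difference_spectrum <- function(sample, reference, interpolate = FALSE) {
  stopifnot(inherits(sample, "spectrum"), inherits(reference, "spectrum"))
  if (identical(sample$axis, reference$axis)) {
    return(spectrum(sample$axis, sample$signal - reference$signal, sample$kind))
  }
  if (!interpolate) {
    abort_sb("axis grids differ; set interpolate = TRUE to resample the reference",
             "specbind_incompatible_grid")
  }
  lo <- max(min(sample$axis), min(reference$axis))
  hi <- min(max(sample$axis), max(reference$axis))
  idx <- which(sample$axis >= lo & sample$axis <= hi)
  if (length(idx) < 3L) {
    abort_sb("grids share fewer than 3 points", "specbind_incompatible_grid")
  }
  ref <- stats::approx(reference$axis, reference$signal,
                       xout = sample$axis[idx], ties = "ordered")$y
  spectrum(sample$axis[idx], sample$signal[idx] - ref, sample$kind)
}

#' Locate a band maximum with sub-grid refinement
#'
#' Finds the maximum inside the window and refines its position by a
#' three-point parabola through the grid maximum and its neighbours. When
#' the parabola is degenerate (flat or non-concave) or the maximum sits on
#' the window edge, the grid position is returned; an edge maximum attaches
#' an `edge_warning`.
#'
#' @param spec a `spectrum`.
#' @param window `c(low, high)` in axis units; needs >= 5 grid points inside.
#' @return list with `position` (axis units), `value` (signal at the grid
#'   maximum), `grid_position`, `edge_warning` (logical).
#' @export
find_band_peak <- function(spec, window) {
  stopifnot(inherits(spec, "spectrum"))
  if (window[1] >= window[2]) abort_sb("window low must be < high",
                                       "specbind_invalid_input")
  idx <- which(spec$axis >= window[1] & spec$axis <= window[2])
  if (length(idx) == 0L) {
    abort_sb(sprintf("window [%g, %g] outside the spectrum axis",
                     window[1], window[2]),
             "specbind_out_of_range")
  }
  if (length(idx) < 5L) {
    abort_sb("need at least 5 grid points inside the window",
             "specbind_insufficient_data")
  }
  x <- spec$axis[idx]
  y <- spec$signal[idx]
  i <- which.max(y)
  edge <- i == 1L || i == length(y)
  pos <- x[i]
  if (!edge) {
    # parabola through (x[i-1], x[i], x[i+1]); vertex in closed form
    x1 <- x[i - 1]; x2 <- x[i]; x3 <- x[i + 1]
    y1 <- y[i - 1]; y2 <- y[i]; y3 <- y[i + 1]
    denom <- (x1 - x2) * (x1 - x3) * (x2 - x3)
    a <- (x3 * (y2 - y1) + x2 * (y1 - y3) + x1 * (y3 - y2)) / denom
    b <- (x3^2 * (y1 - y2) + x2^2 * (y3 - y1) + x1^2 * (y2 - y3)) / denom
    if (is.finite(a) && a < 0) {
      v <- -b / (2 * a)
      if (v >= x1 && v <= x3) pos <- v
    }
  }
  list(position = pos, value = y[i], grid_position = x[i], edge_warning = edge)
}

#' Peak shift of a band between free and bound spectra
#'
#' Locates the band maximum in both spectra within one window and reports
#' `shift = peak_bound - peak_free` (a positive shift means the bound-state
#' band moved to higher axis values, e.g. higher wavenumber).
#'
#' @param free a `spectrum` of the free species.
#' @param bound a `spectrum` of the complexed species.
#' @param window `c(low, high)` axis window, or the name of a preset in
#'   [amide_windows] (`"amide_I"`, `"amide_II"`).
#' @param band_name label for the band; defaults to the preset name or
#'   `"custom"`.
#' @return object of class `band_shift` with fields `band_name`, `window`,
#'   `peak_free`, `peak_bound`, `shift`, `edge_warning`.
#' @export
band_shift <- function(free, bound, window = "amide_I", band_name = NULL) {
  if (is.character(window)) {
    if (is.null(band_name)) band_name <- window
    window <- amide_windows[[match.arg(window, names(amide_windows))]]
  }
  if (is.null(band_name)) band_name <- "custom"
  pf <- find_band_peak(free, window)
  pb <- find_band_peak(bound, window)
  structure(
    list(band_name = band_name, window = window,
         peak_free = pf$position, peak_bound = pb$position,
         shift = pb$position - pf$position,
         edge_warning = pf$edge_warning || pb$edge_warning),
    class = "band_shift"
  )
}

#' @export
print.band_shift <- function(x, ...) {
  cat(sprintf("<band_shift %s: %.2f -> %.2f (shift %+.2f)>\n",
              x$band_name, x$peak_free, x$peak_bound, x$shift))
  invisible(x)
}

#' Absorbance trend across a titration
#'
#' Absorbance at one wavelength per quencher concentration, with the OLS
#' slope and a consistency flag: a rising absorbance is the signature of
#' ground-state complex formation (consistent with static quenching),
#' whereas collisional quenching leaves the absorption spectrum unaffected.
#' The flag is advisory evidence only; the binding verdict belongs to
#' [classify_mechanism()].
#'
#' @param series an absorbance-kind `titration_series`.
#' @param wavelength analysis wavelength, nm (e.g. 278 nm for the aromatic
#'   protein band).
#' @return list with `table` (quencher_conc, absorbance), `slope`,
#'   `slope_sign`, `flag` (one of `"static-consistent"`,
#'   `"dynamic-consistent (spectra unaffected)"`, `"decreasing"`).
#' @export
absorbance_trend <- function(series, wavelength) {
  stopifnot(inherits(series, "titration_series"))
  if (series$points[[1]]$spectrum$kind != "absorbance") {
    abort_sb("absorbance_trend needs an absorbance-kind series",
             "specbind_invalid_input")
  }
  tab <- extract_intensity(series, wavelength)
  names(tab) <- c("quencher_conc", "absorbance")
  if (nrow(tab) < 2L) abort_sb("need at least 2 points",
                               "specbind_insufficient_data")
  fit <- stats::lm(absorbance ~ quencher_conc, data = tab)
  slope <- unname(stats::coef(fit)[2])
  # a predicted change negligible against the signal scale counts as flat
  scale <- max(abs(tab$absorbance), .Machine$double.eps)
  if (abs(slope) * diff(range(tab$quencher_conc)) < 1e-9 * scale) slope <- 0
  s <- sign(slope)
  flag <- if (s > 0) "static-consistent"
          else if (s == 0) "dynamic-consistent (spectra unaffected)"
          else "decreasing"
  list(table = tab, slope = slope, slope_sign = s, flag = flag,
       wavelength = wavelength)
}
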