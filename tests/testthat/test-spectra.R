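test_that("spectrum construction enforces its invariants", {
  s <- spectrum(c(300, 344, 500), c(0, 100, 0), "emission")
  expect_s3_class(s, "spectrum")
  expect_equal(s$signal[s$axis == 344], 100)

  expect_error(spectrum(c(300, 300, 500), c(1, 2, 3), "emission"),
               class = "specbind_invalid_input")
  expect_error(spectrum(c(300, 400), c(1, 2), "emission"),
               class = "specbind_insufficient_data")
  expect_error(spectrum(c(300, 400, 500), c(1, NA, 2), "emission"),
               class = "specbind_invalid_input")
  expect_error(spectrum(c(300, 400, 500), c(1, Inf, 2), "emission"),
               class = "specbind_invalid_input")
  expect_error(spectrum(1:3, 1:3, "xray"))
})

test_that("read_spectrum parses two-column text, sorts, and reports bad rows", {
  p <- write_lines_tmp(c("# comment", "300,0.0", "344,100.0", "500,0.0"))
  s <- read_spectrum(p, "emission")
  expect_equal(length(s$axis), 3)
  expect_equal(s$signal[2], 100)

  # descending input gives the same spectrum as ascending
  p2 <- write_lines_tmp(c("500,0.0", "344,100.0", "300,0.0"))
  expect_equal(read_spectrum(p2, "emission"), s)

  # whitespace delimiting works too
  p3 <- write_lines_tmp(c("300 0.0", "344 100.0", "500 0.0"))
  expect_equal(read_spectrum(p3, "emission"), s)

  # non-numeric cell names the offending line
  bad <- write_lines_tmp(c("300,1", "310,2", "320,3", "330,4", "340,5",
                           "350,6", "360,oops"))
  err <- expect_error(read_spectrum(bad, "emission"),
                      class = "specbind_parse_error")
  expect_match(conditionMessage(err), "line 7")

  expect_error(read_spectrum(write_lines_tmp(c("300,1", "310,2")), "emission"),
               class = "specbind_insufficient_data")
  expect_error(read_spectrum(tempfile(), "emission"),
               class = "specbind_missing_file")
})

test_that("write then read round-trips a spectrum at full precision", {
  set.seed(42)
  s <- spectrum(sort(runif(50, 1000, 1900)), rnorm(50), "ir_absorbance")
  p <- tempfile(fileext = ".csv")
  write_spectrum(s, p)
  expect_identical(read_spectrum(p, "ir_absorbance"), s)
})

test_that("titration series validates F0, ordering and shared grids", {
  mk <- function(conc) {
    lapply(conc, function(q) list(
      quencher_conc = q,
      spectrum = spectrum(c(300, 344, 500), c(0, 100, 0), "emission")))
  }
  ok <- titration_series(15e-6, 298, mk(c(0, 15e-6, 30e-6)))
  expect_equal(quencher_concentrations(ok), c(0, 15e-6, 30e-6))

  expect_error(titration_series(15e-6, 298, mk(c(15e-6, 30e-6, 45e-6))),
               class = "specbind_missing_f0")
  expect_error(titration_series(15e-6, 298, mk(c(0, 30e-6, 15e-6))),
               class = "specbind_ordering_error")
  expect_error(titration_series(0, 298, mk(c(0, 15e-6, 30e-6))),
               class = "specbind_invalid_input")
  pts <- mk(c(0, 15e-6, 30e-6))
  pts[[2]]$spectrum <- spectrum(c(301, 344, 500), c(0, 100, 0), "emission")
  expect_error(titration_series(15e-6, 298, pts),
               class = "specbind_incompatible_grid")
})

test_that("manifest round-trip via the study bundle reproduces the series", {
  dir <- tempfile()
  simulate_study_bundle(dir, quenching_ground_truth(
    Kb_per_T = c("298" = 5200), seed = 7L))
  series <- read_titration_manifest(file.path(dir, "T298", "manifest.yml"))
  expect_s3_class(series, "titration_series")
  expect_equal(series$temperature, 298)
  expect_equal(series$protein_conc, 15e-6)
  expect_equal(series$excitation_wavelength, 280)
  ref <- simulate_quenching_titration(
    quenching_ground_truth(Kb_per_T = c("298" = 5200), seed = 7L), 298)
  expect_equal(extract_intensity(series, 344), extract_intensity(ref, 344))
})

test_that("manifest errors carry the contract classes", {
  dir <- tempfile(); dir.create(dir)
  sp <- file.path(dir, "s.csv")
  write_spectrum(spectrum(c(300, 344, 500), c(0, 100, 0), "emission"), sp)
  write_manifest <- function(concs) {
    p <- file.path(dir, "m.yml")
    yaml::write_yaml(list(
      protein_conc_uM = 15, temperature_K = 298, excitation_nm = 280,
      points = lapply(concs, function(q) list(quencher_conc_uM = q,
                                              file = "s.csv"))), p)
    p
  }
  expect_error(read_titration_manifest(write_manifest(c(15, 30))),
               class = "specbind_missing_f0")
  expect_error(read_titration_manifest(write_manifest(c(0, 30, 15))),
               class = "specbind_ordering_error")
  s <- read_titration_manifest(write_manifest(c(0, 15, 30)))
  expect_equal(quencher_concentrations(s), c(0, 15e-6, 30e-6))
})

test_that("extract_intensity is exact on grid and linear between points", {
  mk <- function() spectrum(c(340, 350, 360), c(10, 20, 40), "emission")
  series <- titration_series(15e-6, 298, list(
    list(quencher_conc = 0, spectrum = mk()),
    list(quencher_conc = 1e-6, spectrum = mk()),
    list(quencher_conc = 2e-6, spectrum = mk())))
  expect_equal(extract_intensity(series, 350)$signal, rep(20, 3))
  expect_equal(extract_intensity(series, 345)$signal, rep(15, 3))
  expect_equal(extract_intensity(series, 355)$signal, rep(30, 3))
  expect_error(extract_intensity(series, 299),
               class = "specbind_out_of_range")

  # straight-line spectra: interpolation reproduces the line everywhere
  lin <- spectrum(seq(300, 500, 10), 2 * seq(300, 500, 10) - 100, "emission")
  series2 <- titration_series(15e-6, 298, lapply(c(0, 1e-6, 2e-6), function(q)
    list(quencher_conc = q, spectrum = lin)))
  for (w in c(305.5, 347.2, 499)) {
    expect_equal(extract_intensity(series2, w)$signal, rep(2 * w - 100, 3))
  }
})
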