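test_that("molar ellipticity conversion is 100 theta / (C l)", {
  expect_equal(to_molar_ellipticity(0, 1e-5, 0.1), 0)
  expect_equal(to_molar_ellipticity(7, 100, 1), 7)
  expect_equal(to_molar_ellipticity(-5, 15e-6, 0.1), 100 * (-5) / (15e-6 * 0.1))
  expect_error(to_molar_ellipticity(1, 0, 0.1), class = "specbind_invalid_input")
  expect_error(to_molar_ellipticity(1, 1e-5, -1), class = "specbind_invalid_input")
  # spectrum method applies pointwise
  b <- cd_basis_synthetic()
  s <- simulate_cd_spectrum(c(1, 0, 0, 0), b)
  m <- to_molar_ellipticity(s, 15e-6, 0.1)
  expect_equal(m$signal, 100 * s$signal / (15e-6 * 0.1))
  expect_equal(m$kind, s$kind)
})

test_that("unmixing recovers vertices and interior compositions exactly", {
  basis <- cd_basis_synthetic()
  # vertex: the pure helix spectrum
  fr <- estimate_secondary_structure(simulate_cd_spectrum(c(1, 0, 0, 0), basis),
                                     basis)
  expect_equal(c(fr$alpha_helix, fr$beta, fr$turn, fr$random), c(1, 0, 0, 0),
               tolerance = 1e-9)
  expect_lt(fr$residual_rms, 1e-10)
  # interior composition typical of a helix-rich albumin
  f <- c(0.368, 0, 0.268, 0.364)
  fr2 <- estimate_secondary_structure(simulate_cd_spectrum(f, basis), basis)
  expect_equal(c(fr2$alpha_helix, fr2$beta, fr2$turn, fr2$random), f,
               tolerance = 1e-6)
  # all four classes present
  f3 <- c(0.3, 0.2, 0.25, 0.25)
  fr3 <- estimate_secondary_structure(simulate_cd_spectrum(f3, basis), basis)
  expect_equal(c(fr3$alpha_helix, fr3$beta, fr3$turn, fr3$random), f3,
               tolerance = 1e-6)
})

test_that("fractions always satisfy the simplex constraints under noise", {
  basis <- cd_basis_synthetic()
  for (seed in 1:25) {
    s <- simulate_cd_spectrum(c(0.368, 0, 0.268, 0.364), basis,
                              noise_sd = 2, seed = seed)
    fr <- estimate_secondary_structure(s, basis)
    f <- c(fr$alpha_helix, fr$beta, fr$turn, fr$random)
    expect_true(all(f >= 0 & f <= 1))
    expect_equal(sum(f), 1, tolerance = 1e-6)
  }
})

test_that("noisy recovery is unbiased at the helix fraction", {
  basis <- cd_basis_synthetic()
  helix <- vapply(1:100, function(seed) {
    s <- simulate_cd_spectrum(c(0.368, 0, 0.268, 0.364), basis,
                              noise_sd = 0.5, seed = seed)
    estimate_secondary_structure(s, basis)$alpha_helix
  }, numeric(1))
  expect_lt(abs(mean(helix) - 0.368), 0.02)
})

test_that("unmixing is equivariant under joint positive rescaling", {
  basis <- cd_basis_synthetic()
  s <- simulate_cd_spectrum(c(0.2, 0.1, 0.3, 0.4), basis)
  s_scaled <- spectrum(s$axis, 7.5 * s$signal, s$kind)
  basis_scaled <- basis_set(basis$axis, 7.5 * basis$components)
  a <- estimate_secondary_structure(s, basis)
  b <- estimate_secondary_structure(s_scaled, basis_scaled)
  expect_equal(c(a$alpha_helix, a$beta, a$turn, a$random),
               c(b$alpha_helix, b$beta, b$turn, b$random), tolerance = 1e-9)
})

test_that("adding admissible components never increases the optimal residual", {
  basis <- cd_basis_synthetic()
  set.seed(9)
  y <- rnorm(length(basis$axis), sd = 5)  # arbitrary target outside the span
  B <- basis$components
  r_full <- specbind:::simplex_lsq(y, B)$residual
  for (drop in 1:4) {
    r_sub <- specbind:::simplex_lsq(y, B[, -drop, drop = FALSE])$residual
    expect_gte(r_sub, r_full - 1e-10)
  }
})

test_that("grid handling: window overlap and basis interpolation", {
  basis <- cd_basis_synthetic()
  # spectrum on a shifted grid still fits via interpolation
  ax <- seq(200.5, 259.5, by = 1)
  f <- c(0.5, 0.1, 0.2, 0.2)
  interp <- vapply(seq_len(4), function(k)
    stats::approx(basis$axis, basis$components[, k], xout = ax)$y,
    numeric(length(ax)))
  s <- spectrum(ax, as.numeric(interp %*% f), "cd_ellipticity_mdeg")
  fr <- estimate_secondary_structure(s, basis)
  expect_equal(c(fr$alpha_helix, fr$beta, fr$turn, fr$random), f,
               tolerance = 1e-3)
  # no overlap -> incompatible grid
  far <- spectrum(seq(300, 400, 1), rep(1, 101), "cd_ellipticity_mdeg")
  expect_error(estimate_secondary_structure(far, basis),
               class = "specbind_incompatible_grid")
  # a near-collinear basis attaches a conditioning warning
  g <- function(center) exp(-0.5 * ((basis$axis - center) / 6)^2)
  bad <- basis_set(basis$axis, cbind(
    alpha_helix = -30 * g(209), beta = -30 * g(209) * (1 + 1e-9),
    turn = 15 * g(205), random = -35 * g(200)))
  s2 <- spectrum(basis$axis, -10 * g(209), "cd_ellipticity_mdeg")
  expect_true(estimate_secondary_structure(s2, bad)$conditioning_warning)
})

test_that("basis files round-trip through write/read", {
  basis <- cd_basis_synthetic()
  p <- tempfile(fileext = ".txt")
  write_basis_set(basis, p)
  back <- read_basis_set(p)
  expect_equal(back$axis, basis$axis)
  expect_equal(back$components, basis$components, tolerance = 1e-12)
})

test_that("titration tracking reports a negative helix trend when helicity is lost", {
  basis <- cd_basis_synthetic()
  # helix falling from 36.8% to 13.3% with random coil picking up the rest
  helix <- seq(0.368, 0.133, length.out = 9)
  labels <- c("free", paste0("1:", 1:8))
  spectra <- stats::setNames(lapply(helix, function(h) {
    f <- c(h, 0, 0.268, 1 - h - 0.268)
    simulate_cd_spectrum(f, basis)
  }), labels)
  tab <- track_titration_structure(spectra, basis)
  expect_equal(nrow(tab), 9)
  expect_equal(tab$ratio, labels)
  expect_equal(attr(tab, "helix_trend"), -1)
  expect_equal(tab$alpha_helix, helix, tolerance = 1e-6)
  # degenerate single-spectrum list equals the one-shot estimate
  single <- track_titration_structure(spectra[1], basis)
  one <- estimate_secondary_structure(spectra[[1]], basis)
  expect_equal(single$alpha_helix, one$alpha_helix)
  expect_error(track_titration_structure(list(), basis),
               class = "specbind_invalid_input")
})
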