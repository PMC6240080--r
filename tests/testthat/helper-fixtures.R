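# Fixtures are built in code at test time; nothing binary ships with the
# package.

# A noiseless emission titration with known (Kb, n) at one temperature.
make_series <- function(Kb = 5200, n = 1, temperature = 298,
                        quencher_concs = seq(0, 120e-6, by = 15e-6),
                        noise_sd = 0, seed = 1L) {
  truth <- quenching_ground_truth(
    Kb_per_T = stats::setNames(Kb, as.character(temperature)),
    n = n, noise_sd = noise_sd, seed = seed)
  simulate_quenching_titration(truth, temperature, quencher_concs)
}

# A quenching_fit carcass for classifier tests (no regression needed).
make_fit <- function(Ksv, temperature, tau0 = 1e-8) {
  structure(list(Ksv = Ksv, Ksv_se = 0, intercept = 1, r_squared = 1,
                 tau0 = tau0, Kq = Ksv / tau0, temperature = temperature),
            class = "quenching_fit")
}

write_lines_tmp <- function(lines, ext = ".csv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
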