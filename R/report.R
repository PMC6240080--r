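# Full-study orchestration: run every available stage from one config,
# log each decision, emit deterministic delimited tables + a markdown
# summary.
#
# Report formatting is fixed (Ksv as x10^4 with 4 decimals, Kb as x10^3
# with 2 decimals, energies in kJ/mol with 2 decimals, dS in J mol^-1 K^-1
# with 2 decimals) so two runs on identical inputs are byte-identical and
# text-diffable.

#' Read an analysis configuration
#'
#' YAML keys: `quenching_manifests` (list of titration manifest paths, one
#' per temperature; required, >= 1), `tau0` (s, default 1e-8),
#' `diffusion_limit` (L mol^-1 s^-1, default 2e10), `wavelength` (nm,
#' optional; default = emission max of each F0 spectrum), `output_dir`,
#' `seed`, and optional blocks `uv` (`manifest`, `wavelength` default 278),
#' `cd` (`basis` path or omitted for the synthetic basis, `spectra` mapping
#' label -> path, `window`), `ir` (`free`, `bound`, `windows`). Relative
#' paths resolve against the config file's directory.
#'
#' @param path config file path.
#' @return a named list (class `analysis_config`).
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) {
    abort_sb(sprintf("config not found: %s", path), "specbind_missing_file")
  }
  cfg <- yaml::read_yaml(path)
  cfg$.base <- dirname(normalizePath(path))
  cfg$.config_path <- normalizePath(path)
  structure(cfg, class = "analysis_config")
}

resolve_path <- function(p, base) {
  if (is.null(base) || grepl("^/", p)) p else file.path(base, p)
}

require_file <- function(p, stage) {
  if (!file.exists(p)) {
    abort_sb(sprintf("[%s] required file missing: %s", stage, p),
             "specbind_missing_file")
  }
  p
}

#' Run the full spectroscopic binding analysis
#'
#' Executes the available stages in order -- Stern-Volmer quenching fit per
#' temperature, mechanism classification, double-log binding fit per
#' temperature, van't Hoff regression with force classification, UV
#' absorbance trend, CD structure tracking, IR band shifts -- skipping
#' stages whose inputs are absent with a logged notice. Writes delimited
#' tables, a run log and a markdown summary to the output directory and
#' returns everything as a `specbind_report`.
#'
#' @param config an `analysis_config` (see [read_analysis_config()]) or a
#'   named list with the same keys.
#' @return object of class `specbind_report`: fields `quenching` (per-T
#'   table), `mechanism`, `thermo`, `uv`, `structure`, `bands`, `notices`,
#'   `provenance`.
#' @export
run_full_analysis <- function(config) {
  cfg <- config
  base <- cfg$.base
  if (is.null(cfg$quenching_manifests) || length(cfg$quenching_manifests) < 1L) {
    abort_sb("config needs at least one quenching manifest",
             "specbind_invalid_input")
  }
  tau0 <- if (is.null(cfg$tau0)) 1e-8 else cfg$tau0
  dlim <- if (is.null(cfg$diffusion_limit)) 2e10 else cfg$diffusion_limit
  wl <- cfg$wavelength
  notices <- character(0)
  note <- function(msg) notices <<- c(notices, msg)

  # --- quenching + binding per temperature -------------------------------
  sv_fits <- list()
  bd_fits <- list()
  for (mp in cfg$quenching_manifests) {
    p <- require_file(resolve_path(mp, base), "quenching")
    series <- read_titration_manifest(p)
    sv <- fit_stern_volmer(series, tau0 = tau0, wavelength = wl)
    bd <- fit_binding(series, wavelength = wl)
    key <- as.character(series$temperature)
    sv_fits[[key]] <- sv
    bd_fits[[key]] <- bd
    note(sprintf("quenching @ %s K: wavelength %.6g nm, IFE %s, %d point(s) excluded from double-log fit",
                 key, sv$wavelength,
                 if (sv$ife_applied) "applied" else "not applied",
                 bd$points_excluded))
    if (sv$intercept_warning) {
      note(sprintf("quenching @ %s K: Stern-Volmer intercept %.3f deviates from 1 by > 0.05",
                   key, sv$intercept))
    }
  }
  ord <- order(as.numeric(names(sv_fits)))
  sv_fits <- sv_fits[ord]
  bd_fits <- bd_fits[ord]
  quench_tab <- data.frame(
    temperature_K = as.numeric(names(sv_fits)),
    Ksv_L_per_mol = vapply(sv_fits, function(f) f$Ksv, numeric(1)),
    Ksv_se = vapply(sv_fits, function(f) f$Ksv_se, numeric(1)),
    Kq_L_per_mol_s = vapply(sv_fits, function(f) f$Kq, numeric(1)),
    r_squared_sv = vapply(sv_fits, function(f) f$r_squared, numeric(1)),
    Kb_L_per_mol = vapply(bd_fits, function(f) f$Kb, numeric(1)),
    n = vapply(bd_fits, function(f) f$n, numeric(1)),
    r_squared_binding = vapply(bd_fits, function(f) f$r_squared, numeric(1)),
    row.names = NULL
  )

  # --- mechanism + van't Hoff (need >= 2 temperatures) -------------------
  mechanism <- NULL
  thermo <- NULL
  if (length(sv_fits) >= 2L) {
    mechanism <- classify_mechanism(sv_fits, diffusion_limit = dlim)
    thermo <- fit_vant_hoff(quench_tab$temperature_K, quench_tab$Kb_L_per_mol)
  } else {
    note("single temperature: mechanism and van't Hoff stages skipped")
  }

  # --- UV absorbance trend ----------------------------------------------
  uv <- NULL
  if (!is.null(cfg$uv)) {
    p <- require_file(resolve_path(cfg$uv$manifest, base), "uv")
    uv_wl <- if (is.null(cfg$uv$wavelength)) 278 else cfg$uv$wavelength
    uv <- absorbance_trend(read_titration_manifest(p), uv_wl)
    note(sprintf("uv: slope %.4g at %g nm -> %s", uv$slope, uv_wl, uv$flag))
  } else {
    note("no UV manifest: absorbance trend stage skipped")
  }

  # --- CD structure ------------------------------------------------------
  structure_tab <- NULL
  if (!is.null(cfg$cd)) {
    basis <- if (is.null(cfg$cd$basis)) {
      note("cd: no basis file given, using the synthetic canonical basis")
      cd_basis_synthetic()
    } else {
      read_basis_set(require_file(resolve_path(cfg$cd$basis, base), "cd"))
    }
    window <- if (is.null(cfg$cd$window)) c(200, 260) else unlist(cfg$cd$window)
    spectra <- lapply(cfg$cd$spectra, function(sp) {
      read_spectrum(require_file(resolve_path(sp, base), "cd"),
                    "cd_ellipticity_mdeg")
    })
    structure_tab <- track_titration_structure(spectra, basis, window)
    note(sprintf("cd: helix trend %+d across %d spectra",
                 attr(structure_tab, "helix_trend"), nrow(structure_tab)))
  } else {
    note("no CD block: structure stage skipped")
  }

  # --- IR band shifts ----------------------------------------------------
  bands <- NULL
  if (!is.null(cfg$ir)) {
    free <- read_spectrum(require_file(resolve_path(cfg$ir$free, base), "ir"),
                          "ir_absorbance")
    bound <- read_spectrum(require_file(resolve_path(cfg$ir$bound, base), "ir"),
                           "ir_absorbance")
    wins <- if (is.null(cfg$ir$windows)) names(amide_windows) else cfg$ir$windows
    bands <- lapply(wins, function(w) band_shift(free, bound, w))
    names(bands) <- vapply(bands, function(b) b$band_name, character(1))
    for (b in bands) {
      note(sprintf("ir %s: peak %.2f -> %.2f cm^-1 (shift %+.2f)",
                   b$band_name, b$peak_free, b$peak_bound, b$shift))
    }
  } else {
    note("no IR block: band-shift stage skipped")
  }

  provenance <- list(
    package_version = as.character(utils::packageVersion("specbind")),
    seed = if (is.null(cfg$seed)) NA_integer_ else cfg$seed,
    config_md5 = if (!is.null(cfg$.config_path))
      unname(tools::md5sum(cfg$.config_path)) else NA_character_,
    tau0 = tau0, diffusion_limit = dlim
  )

  report <- structure(
    list(quenching = quench_tab, mechanism = mechanism, thermo = thermo,
         uv = uv, structure = structure_tab, bands = bands,
         notices = notices, provenance = provenance),
    class = "specbind_report"
  )
  if (!is.null(cfg$output_dir)) {
    write_report(report, resolve_path(cfg$output_dir, base))
  }
  report
}

fmt_num <- function(x, digits = 4) sprintf(paste0("%.", digits, "f"), x)

#' Write a report's tables and summary to a directory
#'
#' @param report a `specbind_report`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "specbind_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  q <- report$quenching
  qt <- data.frame(
    temperature_K = q$temperature_K,
    Ksv_x1e4 = fmt_num(q$Ksv_L_per_mol / 1e4, 4),
    Ksv_se_x1e4 = fmt_num(q$Ksv_se / 1e4, 4),
    Kq_x1e12 = fmt_num(q$Kq_L_per_mol_s / 1e12, 4),
    Kb_x1e3 = fmt_num(q$Kb_L_per_mol / 1e3, 2),
    n = fmt_num(q$n, 4),
    R2_sv = fmt_num(q$r_squared_sv, 4),
    R2_binding = fmt_num(q$r_squared_binding, 4)
  )
  utils::write.table(qt, file.path(dir, "quenching.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  lines <- c("# specbind report", "",
             "## Quenching and binding (per temperature)", "",
             paste(capture_table(qt), collapse = "\n"))
  if (!is.null(report$thermo)) {
    th <- report$thermo
    tt <- data.frame(
      temperature_K = as.numeric(names(th$dG_at)),
      dG_kJ_per_mol = fmt_num(th$dG_at / 1000, 2),
      dG_kcal_per_mol = fmt_num(joules_to_kcal(th$dG_at), 2),
      dS_J_per_mol_K = fmt_num(th$dS, 2),
      dH_kJ_per_mol = fmt_num(th$dH / 1000, 2),
      spontaneous = ifelse(th$dG_at < 0, "yes", "no")
    )
    utils::write.table(tt, file.path(dir, "thermo.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    lines <- c(lines, "", "## Thermodynamics (van't Hoff)", "",
               paste(capture_table(tt), collapse = "\n"), "",
               sprintf("Dominant forces: %s", th$force_class))
  }
  if (!is.null(report$mechanism)) {
    lines <- c(lines, "", "## Quenching mechanism", "",
               sprintf("Verdict: %s", report$mechanism$verdict),
               paste("-", report$mechanism$evidence))
  }
  if (!is.null(report$uv)) {
    lines <- c(lines, "", "## UV absorbance trend", "",
               sprintf("Slope %.6g at %g nm: %s", report$uv$slope,
                       report$uv$wavelength, report$uv$flag))
  }
  if (!is.null(report$structure)) {
    st <- report$structure
    stt <- data.frame(
      ratio = st$ratio,
      alpha_helix_pct = fmt_num(100 * st$alpha_helix, 1),
      beta_pct = fmt_num(100 * st$beta, 1),
      turn_pct = fmt_num(100 * st$turn, 1),
      random_pct = fmt_num(100 * st$random, 1),
      residual_rms = fmt_num(st$residual_rms, 4)
    )
    utils::write.table(stt, file.path(dir, "structure.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    lines <- c(lines, "", "## Secondary structure (CD)", "",
               paste(capture_table(stt), collapse = "\n"))
  }
  if (!is.null(report$bands)) {
    bt <- data.frame(
      band = vapply(report$bands, function(b) b$band_name, character(1)),
      peak_free = fmt_num(vapply(report$bands, function(b) b$peak_free, numeric(1)), 2),
      peak_bound = fmt_num(vapply(report$bands, function(b) b$peak_bound, numeric(1)), 2),
      shift = fmt_num(vapply(report$bands, function(b) b$shift, numeric(1)), 2)
    )
    utils::write.table(bt, file.path(dir, "bands.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    lines <- c(lines, "", "## IR band shifts", "",
               paste(capture_table(bt), collapse = "\n"))
  }
  lines <- c(lines, "", "## Provenance", "",
             sprintf("- specbind %s", report$provenance$package_version),
             sprintf("- seed: %s", report$provenance$seed),
             sprintf("- config md5: %s", report$provenance$config_md5),
             sprintf("- tau0: %g s; diffusion limit: %g L/mol/s",
                     report$provenance$tau0, report$provenance$diffusion_limit))
  writeLines(lines, file.path(dir, "report.md"))
  writeLines(report$notices, file.path(dir, "run.log"))
  invisible(dir)
}

capture_table <- function(df) {
  widths <- pmax(nchar(names(df)),
                 vapply(df, function(col) max(nchar(as.character(col))), 0))
  pad <- function(v) mapply(formatC, as.character(v), width = widths,
                            MoreArgs = list(flag = "-"))
  header <- paste(pad(names(df)), collapse = "  ")
  rows <- apply(df, 1, function(r) paste(pad(r), collapse = "  "))
  c(header, rows)
}

#' @export
print.specbind_report <- function(x, ...) {
  cat("<specbind_report>\n")
  print(x$quenching)
  if (!is.null(x$mechanism)) cat(sprintf("mechanism: %s\n", x$mechanism$verdict))
  if (!is.null(x$thermo)) {
    cat(sprintf("dH = %.2f kJ/mol, dS = %.2f J/(mol K), forces: %s\n",
                x$thermo$dH / 1000, x$thermo$dS, x$thermo$force_class))
  }
  invisible(x)
}
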