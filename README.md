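# specbind

Spectroscopic analysis of small-molecule binding to serum albumin (and
similar fluorescent proteins), as an R package.

When a drug candidate is titrated into a protein solution, its binding
leaves quantitative fingerprints in several kinds of spectra. specbind
turns those spectra into binding parameters:

* **Fluorescence quenching** — Stern–Volmer regression
  `F0/F = 1 + Ksv[Q]` gives the quenching constant `Ksv` and the
  bimolecular rate constant `Kq = Ksv/τ0`; the double-log (modified
  Stern–Volmer) regression `log10((F0−F)/F) = log10 Kb + n·log10[Q]`
  gives the binding constant `Kb` and stoichiometry `n`. The
  static-vs-dynamic mechanism is called from the temperature trend of
  `Ksv` and the comparison of `Kq` with the ~2×10¹⁰ L mol⁻¹ s⁻¹
  diffusion limit. Inner-filter correction
  `Fcorr = Fobs·exp((Aex+Aem)/2)` is available when absorbance data
  accompany the titration.
* **Thermodynamics** — van't Hoff regression of `log10 Kb` on `1/T`
  yields ΔH° and ΔS°; ΔG° is computed both as `ΔH° − TΔS°` and as
  `−RT ln Kb`, and the dominant binding forces are classified from the
  signs of ΔH° and ΔS° (both negative → hydrogen bonds + van der Waals;
  both positive → hydrophobic; ΔH°<0, ΔS°>0 → electrostatic).
* **Circular dichroism** — molar-ellipticity conversion
  `[θ] = 100·θ/(C·l)` and secondary-structure fractions by least squares
  against four basis spectra under hard simplex constraints (non-negative
  fractions summing to 1, solved exactly by active-set enumeration).
* **UV / FT-IR** — absorbance trend at a fixed wavelength (rising
  absorbance corroborates ground-state complex formation), difference
  spectra, and amide-band peak positions with sub-grid parabolic
  refinement to resolve free→bound shifts.

A synthetic-data generator with known ground truth
(`quenching_ground_truth()`, `simulate_study_bundle()`, ...) makes every
stage verifiable by parameter recovery, so the pipeline is fully tested
without any proprietary instrument data. See the methods vignette
(`vignettes/specbind-methods.Rmd`) for the models, assumptions and design
choices.

## Worked example

Simulate a three-temperature titration study (15 µM protein, 0–120 µM
ligand, binding constants 34160 / 5200 / 1670 L/mol at 288 / 298 / 308 K)
and run the whole pipeline on the files it wrote:

```r
library(specbind)

root <- file.path(tempdir(), "study")
simulate_study_bundle(root, quenching_ground_truth(seed = 11L))

rep <- run_full_analysis(list(
  quenching_manifests = as.list(
    file.path(root, sprintf("T%03d", c(288, 298, 308)), "manifest.yml")),
  output_dir = file.path(root, "out")))

rep$quenching[, c("temperature_K", "Ksv_L_per_mol", "Kb_L_per_mol", "n")]
#>   temperature_K Ksv_L_per_mol Kb_L_per_mol n
#> 1           288         34160        34160 1
#> 2           298          5200         5200 1
#> 3           308          1670         1670 1

print(rep$mechanism)
#> <mechanism_call: static>
#>   Ksv: 3.416e+04, 5200, 1670 across 288, 298, 308 K -> decreasing trend
#>   Kq 3.416e+12, 5.2e+11, 1.67e+11 vs 2e+10: all exceed the diffusion limit

print(rep$thermo)
#> <thermo_params: dH = -111.56 kJ/mol, dS = -301.44 J/(mol K), forces: hbond_vdw>
#>   dG(288 K) = -24.75 kJ/mol (spontaneous)
#>   dG(298 K) = -21.73 kJ/mol (spontaneous)
#>   dG(308 K) = -18.72 kJ/mol (spontaneous)
```

The fits recover the generative constants exactly (noiseless bundle, and
the generator's law makes both regressions exact by construction). The
mechanism is static: `Ksv` falls with temperature and every `Kq` is far
above the diffusion ceiling. The van't Hoff fit classifies the binding as
enthalpy-driven (`hbond_vdw`: hydrogen bonding + van der Waals) and
spontaneous at all three temperatures; the cross-check route gives

```r
joules_to_kcal(gibbs_from_kb(rep$quenching$Kb_L_per_mol[2], 298))
#> [1] -5.07
```

kcal/mol at 298 K. Fixed-format tables (`quenching.tsv`, `thermo.tsv`,
`report.md`, `run.log`, ...) land in `output_dir`; regeneration from the
same inputs is byte-identical. A thin command-line wrapper with
`simulate` / `quench` / `thermo` / `cd` / `bands` / `report` subcommands
lives at `inst/cli/specbind`.

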