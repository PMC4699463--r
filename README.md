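# fneoscreen

Quantitative analysis of **F-neo (fluorescein–neomycin) displacement assays**
for miRNA-binding compound libraries: probe-binding isotherms, binding-site
stoichiometry, pKa-shift electrostatics, Z′-factor plate QC, plate-normalized
single-point screening with hit calling, IC50 dose–response fitting, and
positional amino-acid preference (σ) ledgers for peptidic-aminoglycoside
conjugate libraries. Seeded synthetic generators emulate every input the
pipeline consumes (titrations, pH series, full 96-well screens), so the whole
analysis is testable without the unpublished raw plate data.

For whom: anyone running fluorescent indicator-displacement screens against
structured RNA (mature or precursor miRNAs, aptamers, the ribosomal A-site)
who needs the standard analysis stack in one tested package.

## The models

**Affinity** — probe binding under ligand depletion (tight-binding quadratic
isotherm), with Ψ the total *site* concentration (RNA × integer site count n):

    F(Ψ) = F0 + (Fb − F0)/(2P) · (S − sqrt(S² − 4ΨP)),   S = Ψ + P + K_D

**Displacement** — two-ligand, one-site-class mass balance solved by a
bracketed monotone root-find on the free-site concentration; IC50s come from
a four-parameter logistic in log10 concentration.

**Electrostatics** — the probe fluorescein's pKa shift on binding maps to an
apparent potential of the binding site: φ = −2.303·ΔpKa (kT/e).

**Screening** — Z′ = 1 − 3(σp + σn)/|μp − μn| for assay QC;
percent binding = 100·(F_drug − F_baseline)/(F_neomycin − F_baseline) with
controls from the same plate; hits at ≥ 110% of neomycin.

**Preference ledger** — per-compound σ deviations from the library mean and
positional class averages (`NeoRX`, `NeoXS`, `NeoX`, …) across miRNAs.

See `vignettes/fneo-displacement-assay.Rmd` for assumptions, defaults and
numerical choices.

## Worked example

Stoichiometry and affinity from a (simulated) saturation titration at the
mature hsa-miR 504 conditions, then a full screen:

```r
library(fneoscreen)

## two-site RNA, K_D 1.5 nM, 100 nM probe, 2% well noise
m <- quadratic_binding_model(f0 = 1000, fb = 250, kd = 1.5, probe_total = 100)
series <- simulate_fneo_titration(m, seq(10, 150, length.out = 15),
                                  n_sites = 2, noise_model(0.02, seed = 504))
estimate_site_multiplicity(series, probe_total = 100)
#> Site multiplicity: n = 2 (kd = 1.117 nM)

electrostatic_potential(6.37, 7.45)
#> delta pKa = +1.08; phi = -2.487 kT/e = -63.89 mV (T = 298.2 K)

## five-plate, 215-compound screen at the published mir504 condition
cond   <- assay_preset("mir504")
kd_neo <- calibrate_competitor_kd(cond, cond$ic50_neomycin)  # 0.343 nM
truth  <- generate_ground_truth_library(kd_neo, seed = 7)
plates <- simulate_screen_plates(truth, cond, noise_model(0.02, seed = 8))

zfactor(plates$signal[plates$role == "positive"],
        plates$signal[plates$role == "negative"])
#> Z' = 0.887 (excellent); mu_p = 932.4 +/- 17.5 (n=10), mu_n = 335.6 +/- 4.91 (n=10)

tab <- summarize_screen(plates)         # percent binding vs on-plate neomycin
sc  <- library_zscores(tab, "mir504")   # sigma ledger
preference_table(list(mir504 = sc), c("NeoX", "NeoRX", "NeoDX", "NeoXS", "NeoXD"))
#>   class_spec mir504
#> 1       NeoX  0.162
#> 2      NeoRX  1.107
#> 3      NeoDX -1.579
#> 4      NeoXS  1.027
#> 5      NeoXD -1.832
```

Reading the output: the multiplicity scan recovers the two probe sites per
RNA; Z′ ≈ 0.89 says the simulated assay window is comfortably screenable;
the class averages recover the generating preference directions — arginine
at position 1 and serine at position 2 help binding (positive σ), aspartate
at either position hurts (strongly negative σ).

The same stages are scriptable: `inst/scripts/fneo` exposes `simulate`,
`fit-kd`, `fit-ic50`, `fit-pka`, `zfactor`, `screen`, `prefs`, `phi` and
`bulges` subcommands, e.g.

```sh
Rscript inst/scripts/fneo phi 6.37 7.45
Rscript inst/scripts/fneo simulate --preset mir504 --seed 7 --out plates.csv
Rscript inst/scripts/fneo screen --plates plates.csv --out screen.csv
```

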