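# npder — kilovoltage photon Monte Carlo for nanoparticle dose enhancement

`npder` simulates orthovoltage x-ray irradiation of a water phantom
uniformly loaded with heavy-metal nanoparticles (gold, platinum,
iodine, silver, iron oxide) and computes the **dose enhancement ratio**
versus depth,

    DER(d) = D_np(d) / D_water(d),

the central-axis depth dose with nanoparticles divided by the dose at
the same depth in plain water. It is aimed at medical-physics users
studying radiosensitization in kilovoltage skin therapy, where the
photoelectric cross section of high-Z elements drives large surface
dose enhancements (and, through self-absorption, DER values below 1 at
depth).

The package contains, end to end:

* **Spectra** — Kramers-law tube continua (tungsten anode) hardened by
  Al/Cu filtration; the two standard study beams are `study_beam(105)`
  (2.4 mm Al) and `study_beam(220)` (1 mm Al + 1.2 mm Cu); inverse-CDF
  energy sampling and half-value-layer diagnostics.
* **Materials** — embedded elemental photon cross-section tables
  (1–300 keV, edge-aware log-log interpolation) combined by the Bragg
  additivity mixture rule; `nanoparticle_mixture("gold", 40)` builds
  water + 40 mg/mL gold with the added-mass density model.
* **Transport** — an analog Monte Carlo engine (C++) with exponential
  free paths, Klein–Nishina Compton sampling, Thomson-angle Rayleigh
  scattering, K-fluorescence escape for Ag/I/Pt/Au, a 1 keV photon
  cutoff, and kerma-approximation voxel scoring with batch statistics.
* **Scoring / study** — central-axis depth-dose reduction,
  `compute_der()`, summary tables with both percent-contrast
  conventions, and `run_der_study()` for the full sweep
  (5 materials × 5 concentrations × 2 beams against per-beam water
  baselines), with CSV/figure/manifest output and bit-reproducible
  seeding.

The default conditions reproduce a published EGSnrc phantom study:
10 × 10 × 12 cm water phantom, 5 cm diameter field, SSD 20 cm, 1 cm
depth bins, concentrations 3–40 mg/mL. See the methods vignette
(`vignettes/nanoparticle-dose-enhancement.Rmd`) for the model,
its assumptions, and known limitations.

## Worked example

Gold nanoparticles at 3 and 40 mg/mL under the filtered 105 kVp beam,
2×10⁶ histories per run (about a second each on one CPU):

```r
library(npder)
cfg <- study_config(materials = "gold", concentrations = c(3, 40), kvps = 105,
                    transport = transport_config(n_histories = 2e6, seed = 1))
res <- run_der_study(cfg)
print(res$summary, digits = 3)
#>             material concentration_mg_per_ml kvp max_der min_der der_0.5cm der_5.5cm
#> gold_3_105      gold                       3 105    1.33   1.041      1.33     1.128
#> gold_40_105     gold                      40 105    3.95   0.572      3.95     0.942
```

Reading the 40 mg/mL row: the first depth bin (0.5 cm) receives almost
four times the water dose; by 5.5 cm the DER has fallen below 1 —
upstream nanoparticles attenuate the beam faster than they enhance the
local dose (the self-absorption or "shielding" effect). The DER curve
itself, with batch-based uncertainties:

```r
head(as.data.frame(res$curves[["gold_40_105"]]), 6)
#>   depth_cm   der rel_unc status
#> 1      0.5 3.955 0.00773     ok
#> 2      1.5 2.372 0.01284     ok
#> 3      2.5 1.755 0.01624     ok
#> 4      3.5 1.371 0.01739     ok
#> 5      4.5 1.091 0.02830     ok
#> 6      5.5 0.942 0.03053     ok
```

A deterministic cross-check of the first bin, the spectrum-weighted
kerma ratio, is available without any Monte Carlo:

```r
surface_der_estimate(study_beam(105), nanoparticle_mixture("gold", 3))
#> [1] 1.402  # MC first bin: 1.33 — the estimate ignores first-bin self-attenuation
```

A thin command-line front end is installed with the package
(`system.file("cli", "npder", package = "npder")`) with subcommands
`spectrum`, `simulate`, `study` and `summarize`; the shipped
`inst/extdata/study.yaml` encodes the full reference study.

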