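# imsccs

Automated collision cross section (CCS) determination from ion
mobility spectrometry–mass spectrometry (IMS-MS) feature tables.

An ion drifting through a buffer gas under a weak electric field
separates by its orientation-averaged collision cross section Ω. In the
low-field limit the Mason–Schamp relation ties Ω to the reduced mobility
K₀:

    Ω = (3 z e) / (16 N₀) · sqrt(2π / (μ k T)) · 1 / K₀

with z the charge state, e the elementary charge, N₀ the buffer-gas
number density at standard conditions, μ the ion/gas reduced mass, k the
Boltzmann constant and T the drift-gas temperature. CCS values are a
reproducible structural descriptor that sharpens molecular
identification in metabolomics and proteomics — but extracting them from
raw feature tables is instrument-dependent and usually manual. This
package automates the three standard experiment styles:

* **Stepped-field drift tube** — the same sample is acquired at several
  drift voltages; arrival time is linear in the field term
  `x = L² (273.15/760) P/(T V)` with slope 1/K₀ and intercept t₀ (the
  time spent outside the drift cell). A combination search over
  candidate features per field finds the feature sets whose regression
  passes an R² threshold; each passing fit is a conformer and its CCS
  follows directly from Mason–Schamp.
* **Single-field drift tube** — arrival time is calibrated linearly
  against the reduced CCS `Ω′ = Ω sqrt(mI/(mI+mB)) / z` of reference
  ions (e.g. Agilent tune-mix), then applied untargeted to all detected
  features. An *enhanced* mode regresses on `(P/T)·Ω′` instead, so that
  drift-gas pressure/temperature drift between the calibrant run and
  each sample run is corrected using each run's own recorded conditions.
  Calibrant runs are assigned to sample runs automatically by polarity
  and acquisition timestamp (following-closest rule). A `tims_scan` mode
  calibrates IMS scan numbers the same way for trapped-IMS data.
* **Traveling-wave (TWIMS/SLIM)** — the arrival-time/CCS relation is
  non-linear; the package fits either a polynomial in the corrected
  arrival time `t′ = tA − C·sqrt(m/z)/1000 − t_acc` (EDC delay C,
  accumulation time t_acc) or the linearized power law
  `ln Ω′ = X ln t′ + ln Y`, followed by the final linear map
  `Ω = a·t″ + b` with `t″ = (t′)^X z / sqrt(μ)`. Features outside the
  calibrant range are flagged `extrapolated`.

Feature tables are read from MZmine-style CSV or a simplified CEF XML
dialect (`inst/extdata/cef-dialect.md`); instrument conditions from a
frame-metadata CSV; results are written as deterministic tab-delimited
tables. Synthetic campaign generators with known ground truth
(`synth_stepped_campaign()`, `synth_single_field_campaign()`,
`synth_twims_campaign()`) make every calibration mode testable without
instrument data.

## Worked example

Generate a noiseless 7-field stepped campaign (850–1450 V in 100 V
steps) for three tune-mix ions and recover their CCS:

```r
library(imsccs)

ions <- data.frame(name = c("TuneMix322", "TuneMix622", "TuneMix922"),
                   mz = c(322.0481, 622.0290, 922.0098), charge_z = 1L,
                   ccs = c(153.7, 203.0, 243.6), polarity = "positive")
targets <- data.frame(name = ions$name,
                      neutral_mass = ions$mz - 1.007276466)

camp <- synth_stepped_campaign(ions, seed = 4)
fit <- fit_stepped_field(camp$features, camp$metadata, targets)
fit
#> Stepped-field CCS fit: 15 target ion(s), 7 field(s), 3 conformer(s) passing R^2 >= 0.99

df <- as.data.frame(fit)
df[, c("name", "adduct", "mz", "ccs", "K0", "r_squared", "n_fields")]
#>         name adduct       mz   ccs        K0 r_squared n_fields
#> 1 TuneMix322 [M+H]+ 322.0481 153.7 1.3669949         1        7
#> 2 TuneMix622 [M+H]+ 622.0290 203.0 1.0148420         1        7
#> 3 TuneMix922 [M+H]+ 922.0098 243.6 0.8397519         1        7
```

Each row is one conformer: `K0` is the reduced mobility from the
regression slope (cm²/V·s), `ccs` its Mason–Schamp CCS (Å²) at the mean
drift-gas temperature of the fields used, `r_squared` the regression
quality and `n_fields` how many fields contributed. The planted values
(153.7, 203.0, 243.6 Å²) are recovered exactly on noiseless data.

The same analysis from a shell:

```sh
Rscript inst/cli/imsccs.R synth --out demo --seed 4
Rscript inst/cli/imsccs.R stepped --features demo/features.csv \
    --metadata demo/metadata.csv --targets demo/targets.csv --out demo/out
```

which writes `results.tsv`, a `report.txt` with per-molecule replicate
statistics (mean CCS and %RSD), and optional calibration JSON/plots for
the calibrated workflows.

Comparing two CCS determinations uses the standard percent-difference
arithmetic:

```r
delta_ccs_percent(63.53, 58.44)
#> [1] 8.709788
```

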