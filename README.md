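# ftirQuant

Quantitative analysis of ATR-FTIR spectra of cultured cells under
dose-response treatments, for vibrational-spectroscopy and chemometrics
practitioners. The package covers the complete workflow around a
macromolecular profiling experiment — here, low-dose DMSO (0.1–1.5 % v/v)
on epithelial cell lines — in which marker bands report each macromolecule
class:

* **nucleic acids** — PO₂⁻ antisymmetric stretch (1242–1238 cm⁻¹), ribose
  ring (915 cm⁻¹);
* **DNA conformation** — A-form 1240, B-form 1221, and the Z-form-enhanced
  band at 1066 cm⁻¹, summarized as the fold change of
  r = I₁₀₆₆ / (I₁₂₄₀ + I₁₂₂₁) over untreated cells;
* **protein secondary structure** — amide I components at 1657/1649 (α-helix)
  and 1636/1629 cm⁻¹ (β-sheet), summarized as the conversion
  100·(1 − ᾱ(dose)/ᾱ(UT));
* **lipids** — olefinic 3009, CH₂ 2921/2852, cholesteryl ester 1172 cm⁻¹,
  with 100·olefinic/total-lipid as the unsaturation ratio.

Preprocessing follows the standard chain (scaled buffer subtraction
flattening the 2125 cm⁻¹ free-water band, Savitzky–Golay second
derivatives, Euclidean vector normalization, percent-of-untreated
scaling), and pattern recognition uses NIPALS PCA (with Hotelling T²
limits) followed by linear / Mahalanobis discriminant classification on PC
scores. Because no public spectra exist for this design, a fully tested
synthetic generator reproduces its statistical structure — 3 biological ×
3 technical replicates per dose group, dose-dependent band effects,
baseline, residual water and noise — so every stage is verifiable against
known ground truth.

## A worked example

```r
library(ftirQuant)

design  <- sampleDesign("HCT116", doses = c(0, 0.1, 0.5, 1.5),
                        bioReps = 3, techReps = 3, seed = 1)
spectra <- generateExperiment(design)           # 36 spectra + PBS reference
tbl     <- percentOfUntreated(quantifyBands(spectra))

secondaryStructureSummary(tbl)[, c("dose", "conversion_pct", "beta_gain_pct")]
#>   dose conversion_pct beta_gain_pct
#> 1  0.0           0.00          0.00
#> 2  0.1          15.75         22.06
#> 3  0.5          29.90         40.99
#> 4  1.5          39.19         57.00
```

The recovered α→β conversion tracks the generator's ground truth
(15 / 30 / 40 % at 0.1 / 0.5 / 1.5 % v/v); the β gain is the conservation
diagnostic expected when the lost α intensity reappears in the β bands.

```r
zdnaEnhancementRatio(tbl)[, c("dose", "fold_change")]
#>   dose fold_change
#> 1  0.0       1.000
#> 2  0.1       1.176
#> 3  0.5       1.435
#> 4  1.5       1.946
```

The Z/(A+B) fold rises above the Z-band multiplier alone because the A/B
denominators also fall with dose — the ratio reflects both conformational
enrichment and total nucleic-acid loss.

```r
groupSummary(tbl, "zdna")[, c("dose", "n", "mean", "sem", "p", "tier")]
#>   dose n mean  sem        p tier
#> 1  0.0 3  100 3.61       NA <NA>
#> 2  0.1 3  116 1.01 1.21e-02    *
#> 3  0.5 3  135 4.18 3.32e-03   **
#> 4  1.5 3  161 1.50 9.59e-05 ****
```

Technical replicates are averaged within biological replicate (n = 3), and
each dose is tested against untreated with an unpaired t test; tiers use
the closed thresholds \*≤0.05 … \*\*\*\*≤0.0001.

```r
d3 <- sampleDesign("HCT116", doses = c(0, 0.5, 1.5), seed = 1)
discriminateGroups(generateExperiment(d3), region = c(4000, 650),
                   labels = "dose")$accuracyHeldout
#> [1] 100
```

Whole-region PCA + PC-score LDA separates untreated, 0.5 % and 1.5 %
groups with 100 % held-out accuracy.

## Command line

`inst/scripts/ftirquant.R` wraps the exported functions as subcommands
(`simulate`, `preprocess`, `quantify`, `classify`, `stats`, `run`) with
`--config`, `--seed`, `--out-dir`, `--region`, `--format` flags; spectra
interchange is long-format CSV (JCAMP-DX read-only).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch through the installed package: the recovered
α→β conversion at 0.1 / 0.5 / 1.5 % v/v on the emulated replicate design
with default noise, and the 20-seed mean held-out LDA accuracies for
dose-group discrimination (whole region) and cell-line discrimination
(lipid region, 3030–2830 cm⁻¹), writing one JSON number per target.

## Documentation

The methods vignette
(`vignettes/ftir-dose-response-chemometrics.Rmd`) documents the generator's
stated world, every tunable parameter with units and defaults, the
estimator definitions and their known biases, and the package's
limitations.
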