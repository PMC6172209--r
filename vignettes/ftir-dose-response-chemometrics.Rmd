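---
title: "Quantifying solvent dose effects on cellular macromolecules from ATR-FTIR spectra"
author: "ftirQuant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying solvent dose effects on cellular macromolecules from ATR-FTIR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftirQuant)
```

# The measurement and the analysis problem

ATR-FTIR spectroscopy of a dried whole-cell film yields an absorbance trace
over 4000–650 cm⁻¹ in which every macromolecular class leaves marker bands:
the amide I envelope (1680–1600 cm⁻¹) reports protein secondary structure,
the C–H stretching block (3030–2830 cm⁻¹) reports lipid acyl chains, the
PO₂⁻ backbone bands (~1240 cm⁻¹) report nucleic acids, and a band near
1066 cm⁻¹ is strongly enhanced when DNA adopts the left-handed Z
conformation. Treating cultured epithelial cells with low doses of DMSO
(0.1–1.5 % v/v) shifts these bands in characteristic, dose-dependent ways;
`ftirQuant` implements the full quantitative workflow for such experiments:

1. **preprocessing** — buffer-reference subtraction with free-water
   flattening, Savitzky–Golay second derivatives, vector / min-max
   normalization, region extraction;
2. **band quantification** — windowed peak-height reads of a versioned
   marker-band table, percent-of-untreated scaling, and derived statistics
   (α→β conversion, Z/(A+B) enhancement fold, olefinic/total-lipid ratio);
3. **chemometrics** — NIPALS PCA with Hotelling T² limits and linear /
   Mahalanobis discriminant classification on PC scores;
4. **group statistics** — mean ± SEM, two-sample t tests against the
   untreated group, closed-threshold significance tiers
   (\*≤0.05, \*\*≤0.01, \*\*\*≤0.001, \*\*\*\*≤0.0001).

Because no public spectral data accompany this design, the package ships a
**synthetic spectrum generator** that is itself first-class, tested code:
every downstream stage is validated against spectra whose ground truth is
known exactly.

# The generator's stated world

`generateExperiment()` produces one spectrum per (cell line × dose ×
biological replicate × technical replicate):

$$y(\nu) \;=\; j_b \sum_i A_i(d)\, g_i(\nu) \;+\; s\,b(\nu) \;+\; w\,W(\nu) \;+\; \varepsilon(\nu)$$

* **Bands** $g_i$ are unit-height gaussians by default (`pseudo_voigt`
  available, since condensed-phase bands have Lorentzian character), on a
  descending 1 cm⁻¹ grid emulating a 4 cm⁻¹-resolution instrument's
  interpolated export.
* **Dose effects** $A_i(d)$: each band's base amplitude times the effect
  model's multiplier at dose $d$ (linearly interpolated between tabulated
  doses), plus the amide I conversion rule: the α components (1657, 1649)
  lose the fraction $c(d)$ of their amplitude and the removed total is added
  to the β components (1636, 1629) in equal halves, conserving summed
  amide I amplitude. The default conversion table is
  $c = 0.15/0.30/0.40$ at $0.1/0.5/1.5\,\%$ v/v (0.35 interpolated at 1.0 %).
* **Replicate structure**: one log-normal amplitude factor $j_b$
  (sdlog 0.02) per biological replicate — sample-amount variation shared by
  that replicate's technical replicates; per-sample log-normal scales for
  baseline and residual water; i.i.d. gaussian noise
  $\varepsilon$ (sd 0.002 a.u.) as the technical-replicate variation.
* **Nuisance structure**: a smooth baseline
  $b(x)=0.010+0.015x+0.005x^2$ over the normalized grid coordinate and a
  residual free-water band $W$ at 2125 cm⁻¹ (FWHM 160, amplitude 0.03). The
  matching buffer (PBS) reference — baseline + water, no cellular bands —
  is returned alongside.

Absolute amplitudes, band widths (FWHM 10 for fingerprint and amide I
component bands) and the multipliers for bands whose change is reported
only as "significant increase/decrease" are **emulation parameters**, not
measured values; they were fixed once, before any acceptance measurement,
to give a plausible cell spectrum with the reported effect directions. Two
placement rules matter downstream and were deliberate: single-band markers
(1172, 1066, 915, 3009 cm⁻¹) sit ≥ 21 cm⁻¹ from their nearest neighbour so
peak-height reads are clean, and the two cell-line profiles differ only in
their lipid-band amplitudes.

What the generator does **not** emulate: interferograms, ATR
penetration-depth physics, Mie scattering, atmospheric CO₂, or — notably —
between-culture *compositional* variance. The single per-replicate
amplitude factor is exactly the kind of variation vector normalization
removes, so percent-intensity group SEMs downstream reflect mainly
technical noise; real biological replicates also vary in composition, and
vs-UT t tests on synthetic data are therefore more uniformly significant
than on real spectra. A green test on this world establishes that the
*pipeline recovers known truth*, not that the effect sizes are
biologically calibrated.

# Preprocessing choices

**Reference subtraction.** The instrument procedure subtracts a buffer
spectrum manually until the free-water band at 2125 cm⁻¹ is flat. We make
the objective explicit: $k$ minimizes the squared residuals of
$y - k\,r$ from a straight line over 2200–2050 cm⁻¹ (closed form via the
line-removing projector). $k$ is stored per sample in
`colData(x)$subtraction_k`.

**Savitzky–Golay.** No parameters are published for the source workflow;
we default to a 9-point window, order-3 polynomial — a common setting for
4 cm⁻¹ data on a 1 cm⁻¹ grid — with edge points fitted on the truncated
window. Both parameters are arguments everywhere. Two numerical facts the
tests pin down: SG reproduces polynomials up to the fit order exactly
(interior *and* edges), and the 9-point cubic *attenuates* the narrow
second-derivative lobe of a FWHM-10 gaussian by roughly 20 % (the quartic
term over the ±4 cm⁻¹ window). The attenuation is common-mode: every
statistic we report is a ratio of second-derivative reads processed
identically, so it cancels — but absolute second-derivative magnitudes
should not be compared across different SG settings.

**Normalization order.** Derivative first, then vector normalization
("second derivative and vector-normalized" spectra); absorbance-sourced
bands are read from vector-normalized absorbance spectra. Min/max
normalization (anchor: amide I/II, 1700–1480 cm⁻¹) is provided for
visualization-style scaling but is not part of the quantitative chain.

**Windows and regions.** All wavenumber intervals are closed, with on-grid
endpoints included. The lipid region is quoted both as 3030–2800 and
3030–2830 cm⁻¹ in the source literature; we default to 3030–2830 and keep
it configurable (`defaultConfig()$regions$lipid`).

# Band quantification

`defaultBandAssignments()` versions the marker table: band, literature
center, search window, source representation, macromolecule class. Windows
default to center ± 4 cm⁻¹ (instrument resolution) except the documented
Z-DNA (1071–1061) and PO₂⁻ antisymmetric (1242–1238) windows. Second
derivative sources read |minimum| in the window (absorbance maxima are
second-derivative minima); absorbance sources read the maximum; ties break
toward the literature center. A PO₂⁻ symmetric assignment (~1080 cm⁻¹)
ships disabled: whether it was analysed separately is unclear in the
source, and its window would graze the Z-DNA band.

Percent-of-untreated scaling divides each band's raw intensities by that
band's untreated group mean (per cell line), so the untreated mean is 100
by construction — an invariant the acceptance suite checks to 10⁻¹².

Three derived statistics, with their estimators:

* **Z-DNA enhancement**: per sample $r = I_{1066}/(I_{1240}+I_{1221})$,
  reported per dose as $\bar r(d)/\bar r(\mathrm{UT})$. Within-sample
  ratios cancel the normalization, so with noise off the generator's Z
  multiplier is recovered to 10⁻⁶ relative error when A/B are held fixed.
  Note the *observed* fold under the full default model exceeds the Z
  multiplier alone because the A/B denominators also fall with dose — the
  statistic deliberately reflects both.
* **Lipid unsaturation**: total lipid is the *sum of percent intensities*
  of 3009 + 2921 + 2852 + 1172 (the source sums "intensities (%)"), and
  the ratio 100·olefinic/total is scale-free.
* **α→β conversion**: $100\,(1-\bar\alpha(d)/\bar\alpha(\mathrm{UT}))$
  with $\alpha = I_{1657}+I_{1649}$ from second-derivative reads; the β
  gain is reported alongside as a conservation diagnostic, not folded into
  the estimate (the source states conversion percentages without a
  formula).

Two known, quantified biases of the peak-height approach on this world:
the β components' positive second-derivative side-lobes overlap the α
minima (the 1649 component is an unresolved shoulder at FWHM 10), and
whole-spectrum vector norms drift ~1 % with dose. Together they bias the
noise-free recovered conversion by ≲ 1.6 points at $c=0.40$ — inside the
±2-point acceptance band, and the reason that band cannot be tightened
without full amide I curve-fitting, which is explicitly out of scope. At
the default noise level the windowed-minimum reads additionally carry a
~2–3 % per-sample CV, leaving the conversion estimate a stochastic spread
of roughly one point at n = 9: the ±2 band is a ≈2-sd band, not a hard
ceiling, and occasional seeds land just outside it.

# Chemometrics

`pcaNipals()` is the sequential power-iteration algorithm with deflation;
convergence is a relative score change < 10⁻⁹ (default) within 1000
iterations, with a warning and a partial model otherwise — trailing
components of noise-degenerate spectra routinely hit this, harmlessly.
Loadings carry a fixed sign convention (largest-magnitude element
positive). The test suite holds NIPALS to the full-SVD oracle at 10⁻⁶ on
50 random matrices. Hotelling's
$T^2_i=\sum_j t_{ij}^2/\lambda_j$ is compared against the F-limit
$k(n-1)/(n-k)\,F_{1-\alpha;k,n-k}$.

`ldaFit()` classifies by smallest squared Mahalanobis distance to class
means under the pooled within-class covariance ("linear") or per-class
covariances ("mahalanobis", falling back to pooled with a warning when a
class has ≤ m training samples). Near-singular covariances get ridge
λ = 10⁻⁸·trace/m. Priors are equal by default (balanced designs); unequal
priors enter as −2 log π. The split is stratified random, default 2/3,
seeded; held-out and all-sample confusion matrices are both reported
because the source does not say which its "100 % accuracy" refers to.

**How many PC scores to feed the classifier.** With 12–18 training spectra,
components beyond the first few are pure noise, and their near-zero
within-class variances dominate the Mahalanobis metric — we measured
held-out accuracy on cleanly separable classes dropping to 67–83 % when all
10 PCs were used. The default is therefore
`m = min(10, rank, floor(min per-class training count / 2))`, keeping the
covariance estimate well-determined; pass `m` explicitly to override. This
replaces the naive `min(10, rank)` default and is the package's one
deliberate deviation from its original design sketch.

# A worked run

```{r, eval = FALSE}
design <- sampleDesign("HCT116", doses = c(0, 0.1, 0.5, 1.5),
                       bioReps = 3, techReps = 3, seed = 1)
spectra <- generateExperiment(design)
tbl <- percentOfUntreated(quantifyBands(spectra))
secondaryStructureSummary(tbl)[, c("dose", "conversion_pct", "beta_gain_pct")]
zdnaEnhancementRatio(tbl)[, c("dose", "fold_change")]
groupSummary(tbl, "zdna")[, c("dose", "n", "mean", "sem", "p", "tier")]

d3 <- sampleDesign("HCT116", doses = c(0, 0.5, 1.5), seed = 1)
discriminateGroups(generateExperiment(d3), region = c(4000, 650),
                   labels = "dose")$accuracyHeldout
```

`scripts/acceptance.R --seed <int> --out <path>` re-runs exactly these
computations from scratch (conversion recovery at the three doses, and the
20-seed mean held-out accuracies for dose and cell-line discrimination)
and writes them as JSON.

# Degenerate inputs and numerical conventions

* Zero-norm spectra, flat spectra, all-zero references, and references
  that are linear across the flatten window are rejected with specific
  errors rather than producing NaNs.
* Zero-variance t-test inputs: equal means → t=0, p=1; unequal means →
  p→0 with a warning.
* Peak ties break toward the literature center; window edges are included.
* Doses outside the effect table use the nearest tabulated value
  (constant extrapolation); inside, linear interpolation.
* All randomness flows from explicit integer seeds
  (`sampleDesign(seed=)`, `ldaFit(seed=)`), and a fixed seed reproduces a
  generated set bit-identically.

# Limitations

* Amide I quantification is peak-height, not curve-fitting: overlapping
  secondary-structure components cross-talk, bounding conversion accuracy
  at ~±2 points on realistic band widths.
* The nucleic-acid PCA region (1250–1200 cm⁻¹) is nearly uninformative
  *on synthetic data* because the default effect model scales the A- and
  B-form bands together, which vector normalization then cancels; real
  spectra contain richer changes there. Dose discrimination on synthetic
  data should use the whole or lipid region.
* Significance patterns of vs-UT t tests are sharper than on real data
  (see the generator's variance model above).
* The JCAMP-DX reader handles fixed-increment AFFN `(X++(Y..Y))` records
  only — enough for instrument exports of this kind, not the compressed
  dialects.
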