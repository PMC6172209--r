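Package: ftirQuant
Title: ATR-FTIR Macromolecular Band Quantification and Chemometrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of attenuated total reflectance Fourier-transform
    infrared (ATR-FTIR) spectra of cultured cells. Provides a synthetic spectrum
    generator for dose-response experiments (Gaussian/Lorentzian/pseudo-Voigt bands,
    baseline, residual water band, replicate structure), spectral preprocessing
    (scaled reference subtraction with free-water flattening, Savitzky-Golay
    smoothing and second derivatives, vector and min/max normalization, region
    extraction), marker-band quantification with percent-of-untreated scaling and
    derived macromolecular statistics (Z-DNA enhancement ratio, lipid unsaturation
    ratios, amide I alpha-helix to beta-sheet conversion), NIPALS principal component
    analysis with Hotelling T2 limits, linear discriminant analysis on principal
    component scores with linear (pooled covariance) and Mahalanobis (per-class
    covariance) classifiers, and group summary statistics with significance tiers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'synthetic.R'
    'preprocess.R'
    'bands.R'
    'chemometrics.R'
    'stats.R'
    'io.R'
    'pipeline.R'
    'ftirQuant-package.R'
    'reexports.R'
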