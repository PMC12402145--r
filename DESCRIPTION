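Package: plaquetime
Title: Timestamping Amyloid Plaques from 15N Isotopologue Signatures in MALDI-MSI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes plaque-age proxies ("nitrogen index") from MALDI mass
    spectrometry imaging spectra of A-beta 1-42 acquired after metabolic 15N
    pulse(-chase) labeling: asymmetric-Gaussian FWHM of the isotopologue
    envelope in linear positive mode, and the 4th/3rd isotopologue peak-area
    ratio in reflector positive mode. Links plaque age to single-plaque
    spatial transcriptomics (quantile normalization, gene-wise Pearson
    correlation, over-representation analysis), to hyperspectral LCO
    amyloid-maturity ratios (linear unmixing, 500/580 nm ratio, plaque-type
    classification), and to radial synapse/dystrophy intensity profiles
    around plaques (distance-transform rings). Includes a seeded
    synthetic-data generator with known ground truth for every modality,
    exact isotopologue pattern computation under partial 15N enrichment,
    asymmetric-least-squares baseline correction, and shared statistical
    primitives including a noncentral-t power utility.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    minpack.lm,
    EBImage,
    limma,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
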