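Package: spatialphos
Title: Structure-Aware Kinase-Specific Phosphorylation Site Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts kinase-specific phosphorylation sites by combining
    sequence-derived features (positional weighted matrix encodings of
    13-mer windows, amino acid composition, solvent accessibility and
    secondary structure windows) with three-dimensional structural
    features (spatial amino acid composition over radial shells of 3-12
    Angstroms around the phosphoacceptor). Features are ranked with an
    F-score statistic and per-kinase support vector machine classifiers
    are trained and evaluated with balanced cross-validation, jackknife
    for small groups, independent testing at a 1:2 class ratio, and a
    cross-classification specificity matrix. Includes a seeded synthetic
    benchmark generator (proteins, sites, C-alpha structures with
    plantable sequence motifs and spatial enrichments) so the full
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    e1071,
    jsonlite,
    seqinr,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
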