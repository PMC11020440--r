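Package: varfit
Title: Protein Variant Fitness Prediction from Structural and
    Evolutionary Features
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts the fitness effect of single amino-acid
    substitutions by a linear combination of structural features
    (relative solvent accessibility and external stability-predictor
    scores) and evolutionary features derived from a multiple sequence
    alignment (conservation index, log-odds ratio, a PROVEAN-style
    substitution score, and the statistical-energy change of a Potts
    model inferred by pseudo-likelihood direct coupling analysis).
    Includes coefficient fitting on deep mutational scanning data,
    interpretability z-scores separating structural from evolutionary
    contributions, evaluation utilities (rank and linear correlations,
    RMSD, balanced accuracy, AUC-ROC, benchmark filters), synthetic
    generators for alignments, structures and training sets, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
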