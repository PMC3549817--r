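Package: knotshape
Title: Consensus Shape and Pseudoknotted Structure Prediction for Homologous ncRNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts the consensus abstract shape of a set of homologous
    non-coding RNAs (pseudoknots allowed) by ranking shape classes built from
    per-sequence folding ensembles with a linear support vector machine, then
    derives a consensus secondary structure inside the predicted shape class
    by constrained agglomerative clustering and progressive alignment of
    structure-annotated (grammar) strings. Includes extended dot-bracket
    parsing with pseudoknot letter classes, abstract shapes at levels 1, 3
    and 5, F-score based feature selection with sequential forward search, a
    toy base-pair-maximisation folder for desk-scale experiments, a synthetic
    homologous-family generator with planted consensus structures, and
    base-pair sensitivity/PPV evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    e1071,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
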