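Package: allocomp
Title: Cluster-Normalized Comparison of Allosteric and Competitive Ligand
    Physicochemistry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Curation, descriptor calculation and redundancy-aware statistics
    for comparing the physicochemical properties of two labeled ligand sets
    (typically allosteric versus competitive binders). Implements SMILES
    washing at pH 7, 29 physicochemical descriptors with size correction,
    ECFP6/Tanimoto chemical-space overlap, two-level protein/ligand
    redundancy clustering (greedy bidirectional sequence-identity families,
    maximum-dissimilarity ligand clusters), cluster-normalized weighting,
    a weighted Wilcoxon rank-sum test, histogram bootstrap confidence
    intervals for medians, and a four-level robustness verdict. A synthetic
    study generator with known ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineOB,
    Biostrings,
    jsonlite,
    graphics,
    methods,
    stats,
    tools,
    utils
Suggests:
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
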