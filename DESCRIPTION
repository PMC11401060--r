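Package: pathomiss
Title: Structure-Aware Classification of Disease-Causing Missense Mutations
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A mutation-analysis toolkit for classifying disease-causing
    versus neutral missense variants in neurodegeneration-associated
    proteins from predicted monomer structures. Generates sequence features
    (residue-group classifications, neighboring amino-acid frequencies,
    AAindex sliding-window deltas, substitution-matrix scores), structural
    descriptors (relative solvent accessibility, residue depth,
    Kabsch-Sander secondary structure, backbone torsions, per-residue
    model confidence), interaction-contact profiles and cumulative
    pharmacophore graph-based signatures at the mutation site; consumes
    externally computed stability, conservation and disorder scores as
    provider tables; trains weighted gradient-boosted tree classifiers
    (one generic model plus per-protein specialised models) with greedy
    forward feature selection; and runs in silico saturation mutagenesis
    with per-site pathogenicity summaries. Includes a synthetic-data
    module (ideal helices, planted-signal mutation sets, matching
    provider tables) so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
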