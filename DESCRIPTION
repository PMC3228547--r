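Package: mddphos
Title: Phosphorylation Site Prediction by Maximal Dependence Decomposition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Discovers kinase substrate motifs in sets of experimentally
    verified phosphorylation sites and predicts new sites in query proteins.
    Fixed-length serine/threonine/tyrosine-centered peptide windows are
    clustered into motif subgroups by maximal dependence decomposition, a
    recursive partitioning on the position pair with the strongest chi-square
    dependence of amino-acid property groups. One ungapped positional
    log-odds profile model is trained per subgroup, a bit-score threshold is
    calibrated per model by five-fold cross-validation over an integer grid,
    and query residues are called phosphosites when at least one model scores
    above its threshold. Includes k-medoids balancing of negative data on
    Hamming distance, a repeated balanced independent-test harness, and a
    synthetic-data generator with planted positional dependencies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
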