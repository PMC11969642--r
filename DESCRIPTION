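Package: pmfvar
Title: Quantifying Variation Between Collagen Peptide Mass Fingerprints
Version: 0.1.0
Authors@R: person("pmfvar", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying variation between collagen peptide mass
    fingerprints (PMFs) as used in ZooMS-style taxonomic identification.
    Reads picked MALDI-ToF peak lists, aligns peaks across samples into
    intensity or presence/absence feature matrices, filters non-biological
    peaks by mass and mass-defect rules, and applies rank-based multivariate
    statistics: Bray-Curtis dissimilarity on the 0-100 scale, global and
    pairwise ANOSIM with permutation significance, SIMPER similarity and
    dissimilarity contribution breakdowns, and non-metric multidimensional
    scaling. Diagnostic marker peaks are selected per taxon by one-vs-rest
    information gain on binary matrices and used for classification with an
    explicit Unclassified outcome. A sequence-divergence layer computes
    pairwise count differences and percent identity from aligned collagen
    chains, rate-based predicted amino-acid change from divergence times,
    and the correlation and t-test summaries linking fingerprint
    dissimilarity to evolutionary distance. A synthetic-data module
    generates taxon-structured collagen-like fingerprints and companion
    sequences with controllable divergence so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    vegan,
    jsonlite,
    optparse
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
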