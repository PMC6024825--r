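Package: venomtx
Title: Assembly, Decontamination and Quality Control of Venom-Gland
    Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Toolkit for the bespoke computational stages of venom-gland
    transcriptome studies: canonical k-mer cross-sample read decontamination
    for index hopping, quality trimming and overlapping read-pair merging, a
    randomly seeded perfect-overlap seed-and-extend assembler tuned for
    recovering multigene toxin families (SVMP, SVSP, CTL and relatives), a
    toxin annotation and near-duplicate collapsing cascade, per-contig chimera
    detection from zero-mismatch read-coverage profiles, completeness and
    assembler-complementarity reporting, and a synthetic venom transcriptome
    simulator with known truth labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
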