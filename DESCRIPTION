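Package: barrettideR
Title: In Silico Discovery of Disulfide-Rich Sponge Peptides from
    Sequencing Data
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Mines transcriptome and genome assemblies for members of
    cysteine-framework peptide families such as the barrettides of the
    deep-sea sponge Geodia barretti. Provides six-frame translated
    homology search (Smith-Waterman with affine gaps), cysteine-framework
    filtering, RiPP-like precursor architecture annotation
    (signal/leader/core/stop/3'UTR), disulfide-corrected monoisotopic
    masses and charge-state m/z, presence calling against MS peak lists,
    eukaryote-vs-prokaryote origin heuristics (poly-A tails, intron
    length classes, GC bimodality), and a fully seeded synthetic-data
    generator with ground-truth manifests so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings
Config/testthat/edition: 3
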