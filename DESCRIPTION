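Package: bmctyper
Title: Profile HMM Identification and Typing of Bacterial Microcompartment Loci
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies bacterial microcompartment (BMC) shell proteins and
    locus components in ordered protein sequence data using profile hidden
    Markov models, builds ordered locus "fingerprints", scores
    inventory-plus-order similarity against a reference registry of BMC
    types, and calls the BMC type by majority vote with ambiguity and
    novelty detection. Includes a deterministic built-in forward-algorithm
    scorer (no external search binary required), an HMMER3 ASCII profile
    importer, a packaged registry of BMC type identifiers, SVG locus-diagram
    rendering, and a seeded synthetic-fixture generator for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    tools,
    utils,
    Rcpp,
    jsonlite,
    seqinr,
    Biostrings,
    IRanges
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    xml2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
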