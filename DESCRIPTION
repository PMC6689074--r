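Package: hoxcrm
Title: Affinity Scanning and Rational Design of Hox-Regulated Cis-Regulatory Modules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Locates Hox-monomer and Hox-cofactor (Exd/Hth) binding sites in
    enhancer DNA using position-specific free-energy models, classifies
    Hox-Exd cores into the three latent-specificity classes (TGATTGAT,
    TGATTAAT, TGATTTAT), and supports rational binding-site engineering:
    single-base class conversion, optimal-flank design, minimal-edit
    knockout of Hox input, site restoration, and overlap-aware side-effect
    auditing. A segment-level expression-logic model combines Hox drive with
    positive JAK/STAT and negative WNT collaborator inputs to predict
    reporter activity across embryonic segments, and a synthetic-data module
    generates enhancer-like fixtures with planted, overlapping Hox-Exd cores
    for validation and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
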