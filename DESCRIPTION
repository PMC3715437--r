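Package: vtdisorder
Title: Structural Disorder Analysis of Vesicle Trafficking Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative analysis of intrinsic structural disorder in the
    proteins of the clathrin-mediated, COPI and COPII vesicle trafficking
    routes. Computes per-residue disorder and disordered-binding-region
    metrics from IUPred/ANCHOR-style score tracks with transmembrane-segment
    masking, summarises disorder content, long disordered regions (LDRs) and
    disordered binding regions (DBRs) per protein, compares functional groups
    and trafficking routes with rank-sum and hypergeometric enrichment tests,
    filters off-pathway interaction partners by confidence and sequence
    identity, maps tissue-specific exons onto protein coordinates and scores
    their disorder and binding-site content, compares disorder between
    human-yeast ortholog pairs, and generates synthetic cohorts with planted
    segment architecture for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
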