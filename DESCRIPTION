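Package: metaport
Title: Curation and Metaphylogeography of COI Metabarcoding Data from Ports
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Post-denoising curation and community analysis of COI
    metabarcoding data from port monitoring programmes. Implements the
    contamination (blank-based), dual-abundance, pseudogene and
    sample-depth filtering cascade on ESV/MOTU tables; classification of
    MOTUs as non-indigenous species (NIS) from reference-database hits;
    rarefied alpha diversity and beta-diversity permutation tests; and
    intra-MOTU haplotype (ESV) diversity with occurrence-based pairwise
    Jost's D differentiation between localities, comparing non-indigenous
    and native species. Ships a synthetic-data generator emulating the
    sampling design so every stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
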