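Package: gatemut
Title: Golden Gate Saturation Mutagenesis Primer Design and Library QC
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design engine for Golden Gate based point and multi-site
    saturation mutagenesis. Detects and silently removes internal type IIS
    recognition sites (domestication) using organism-specific codon usage,
    splits a coding sequence into fragments at mutation clusters, selects
    valid 4 bp junction overhangs, and emits structured mutagenic primers
    with nearest-neighbor melting temperature balancing for the MoClo
    vectors pAGM9121 (BbsI) and pAGM22082_CRed (BsaI). Includes a
    deterministic in-silico assembly simulator (PCR, type IIS digestion,
    overhang-directed ligation) that verifies seamless reconstruction of
    the designed library, and a Quick Quality Control (QQC) module that
    reads pooled-library Sanger chromatograms (ABIF) and reports per-position
    nucleobase distributions at randomized codons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Collate:
    'seqcore.R'
    'codon_usage.R'
    'enzymes.R'
    'tm.R'
    'mutations.R'
    'domestication.R'
    'primerdesign.R'
    'design.R'
    'assembly.R'
    'abif.R'
    'qqc.R'
    'fixtures.R'
    'cli.R'
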