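Package: stopin
Title: Design and In Silico Validation of STOP-IN CRISPR/Cas9 Knock-In Null Alleles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for designing CRISPR/Cas9 knock-in null
    alleles with the universal 43-nucleotide STOP-IN cassette. Scans a target
    gene for Cas9 guide sites (20-nt protospacer + NGG PAM on either strand),
    constructs strand-correct single-stranded DNA repair oligos with short
    homology arms, verifies the predicted null edit in silico (premature stop
    codons in every reading frame plus a frameshift in every isoform), designs
    PCR/RFLP genotyping assays around the insertion, builds wild-type
    reversion oligos against the cassette's exogenous Cas9 site, and
    reproduces knock-in screen-efficiency statistics. Includes a deterministic
    synthetic genome/annotation fixture generator so the whole pipeline is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
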