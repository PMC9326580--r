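Package: eskor
Title: RNA Polymerase II Template Occupancy Versus G+C Content After DSIF Knockdown
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies how RNA polymerase II (Ser2-phosphorylated) template
    occupancy depends on template G+C content when the DSIF subunit Supt4h is
    knocked down. Implements the ESKOR statistic (per-gene log2 ratio of
    ChIP-seq FPKM between knockdown and untreated conditions), sliding-window
    and whole-gene-body G+C content, extreme-G+C 500 bp segment contrasts,
    scaled metagene coverage profiles, gene-length by G+C stratification, and
    RNA abundance fold changes. Ships a synthetic ChIP fragment simulator that
    emulates the assumed signal structure (occupancy linear in G+C at
    condition-specific slopes, optional 5'-to-3' occupancy decay under
    knockdown) so the whole pipeline runs and is validated without external
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
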