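Package: sepomics
Title: Discovery and Quantification of Small ORF-Encoded Peptides from
    Proteogenomic Data
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A proteogenomic toolkit for small open reading frame (sORF)
    discovery. Builds candidate databases of sORF-encoded peptides (SEPs)
    from transcript sequences by three-frame translation with AUG/GUG/UUG
    initiators, performs multi-protease in-silico digestion with missed
    cleavages, computes and matches b/y fragment ions at stated mass
    tolerances, curates peptide-spectrum matches through a quality funnel
    (peptide length, consecutive fragment ions, precursor ppm error,
    search score), screens candidates for novelty against an annotated
    proteome by Smith-Waterman local alignment, and tests label-free
    differential SEP abundance between conditions with Benjamini-Hochberg
    correction. Includes a synthetic-data generator with machine-readable
    ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
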