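Package: mitochar
Title: Characterization of Annotated Circular Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize annotated circular mitochondrial genomes of
    insects, with an emphasis on the lepidopteran 37-gene complement. Reads and
    writes GenBank flat files and FASTA plus feature tables on a circular
    coordinate axis; computes nucleotide composition and AT/GC skews by gene
    partition; classifies start and incomplete stop codons, counts codons, and
    computes relative synonymous codon usage (RSCU) under the invertebrate
    mitochondrial genetic code; folds tRNA genes into constrained cloverleaf
    secondary structures and censuses non-Watson-Crick pairs; catalogues
    intergenic spacers and gene overlaps on the circle and locates tandem
    repeats, homopolymer tracts and conserved motifs; and generates annotated
    synthetic mitogenomes with exhaustive ground truth for testing every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
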