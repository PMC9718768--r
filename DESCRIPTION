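Package: mitochar
Title: Comparative Characterization of Annotated Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparative characterization of annotated circular
    mitochondrial genomes, aimed at the 37-gene insect mitogenome layout.
    Reads and writes GenBank flat files, FASTA, and coordinate-table
    fixtures; computes nucleotide composition and AT/GC strand-asymmetry
    skews per region and per codon position; extracts codons and computes
    relative synonymous codon usage (RSCU) under the invertebrate
    mitochondrial code with split Leu/Ser families; classifies complete and
    incomplete (polyadenylation-completed) stop codons; tabulates gene
    overlaps and intergenic spacers; detects tandem repeats in the control
    region with a mismatch-only model; builds codon-position partitioned
    supermatrices for phylogenetic inference; and generates seeded synthetic
    mitogenomes with planted ground truth for validation.
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
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
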