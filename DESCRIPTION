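Package: tetrapolar
Title: Tetrapolar Mating-Type Genetics and Homeodomain Protein Analysis for Agaricomycete Fungi
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genetic analysis of the tetrapolar (bifactorial) mating
    system of agaricomycete fungi such as the oyster mushroom Pleurotus
    ostreatus. Models haploid mating genotypes at the two unlinked
    mating-type loci (matA and matB), evaluates monokaryon-monokaryon and
    dikaryon-monokaryon (Buller) crosses, reads and writes labelled
    plus/minus compatibility matrices, and infers the minimal number of
    distinct allele classes at each locus that is consistent with an
    observed crossing matrix, using union-find constraint propagation and
    exact backtracking search. Includes a seeded simulator of allele pools,
    dikaryon sampling, tester-panel derivation and crossing matrices, a
    generator of homeodomain-like protein sequences, and protein sequence
    utilities: wildcard motif scanning (e.g. the homeodomain WFXNXR motif),
    Kyte-Doolittle hydropathy profiles with transmembrane/globular calls,
    a compositional nuclear-localization-signal screen, and GFF3 export of
    matA locus gene-cassette models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
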