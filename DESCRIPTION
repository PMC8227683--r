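Package: mitocomp
Title: Comparative Mitogenomics of Circular Insect Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of annotated circular
    mitochondrial genomes: nucleotide composition, strand-asymmetry (AT/GC)
    skews, relative synonymous codon usage under the invertebrate
    mitochondrial code, circular intergenic-spacer and gene-overlap
    accounting, tRNA gene-order rearrangement inference against the
    ancestral pancrustacean arrangement (transpositions, inversions and
    reverse transpositions of genes or gene blocks), substitution-saturation
    screening by correlating GTR+Gamma+I maximum-likelihood pairwise
    distances with uncorrected p-distances, and assembly of partitioned
    supermatrices with codon-position charsets.  A synthetic-mitogenome
    generator simulates fully annotated genomes and aligned per-gene
    datasets along a birth tree so the whole pipeline can be exercised and
    validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
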