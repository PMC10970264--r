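Package: chloroPanel
Title: Chloroplast Marker-Panel Discovery and KASP Assay Design for
    Plastome Alignments
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers SNP and InDel loci from aligned plastid (chloroplast)
    genome panels, assigns group specificity by one-vs-rest Weir-Cockerham
    F_ST, selects minimal discriminating marker panels, designs KASP
    (Kompetitive Allele Specific PCR) allele-specific primers from conserved
    flanking sequence, and traces maternal lineage through trios, reciprocal
    crosses and cytoplasmic-male-sterility hybrids. Includes a synthetic
    plastome-panel generator with planted truth for end-to-end validation,
    quadripartite (LSC/IR/SSC) structure detection, and readers/writers for
    aligned FASTA, sample sheets, BED/GFF3 gene maps, minimal VCF 4.2 and
    the published Varietal Chloroplast Panel marker-table dialect.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
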