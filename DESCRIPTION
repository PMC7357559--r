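Package: mirhom
Title: Homology-Based Annotation of Conserved miRNA Genes with Small
    RNA-Seq Support
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates conserved microRNA genes in a genome by homology to a
    reference set of precursor miRNAs, validates candidate loci as
    thermodynamically stable stem-loop hairpins, quantifies mature miRNA
    expression from multi-individual small RNA sequencing libraries, and
    characterizes the genomic organisation of the resulting miRNA gene set:
    intergenic/intronic/exonic context, antisense (mirror) pairs, 10-kb
    same-strand clusters with homo-/hetero-seed classes, conservation-age
    categories and the correlation between miRNA age and expression level.
    Includes a synthetic-data generator that plants miRNA loci with known
    ground truth in a toy genome and simulates small RNA libraries, so the
    whole pipeline can be exercised end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
SystemRequirements: ViennaRNA (RNAfold and RNAeval on the PATH)
Config/testthat/edition: 3
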