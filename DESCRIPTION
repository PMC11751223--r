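Package: mitescan
Title: MITE Methylation Dynamics and Insertion-Polymorphism Analysis
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying miniature inverted-repeat transposable
    elements (MITEs) as agents of heritable epigenetic and genetic
    variation. Computes per-element DNA methylation levels from
    cytosine-resolution bisulfite reports, quantifies hyper- and
    hypomethylation relative to control lines and the transgenerational
    stability of those shifts, detects MITE transposon insertion
    polymorphisms (TIPs) from soft-clipped read evidence with target-site
    duplication support, genotypes TIP loci across samples to isolate
    treatment-induced insertions, and screens element methylation against
    phenotypes by Pearson correlation. Includes a fully deterministic
    synthetic-data generator (genome, annotations, cytosine reports,
    alignments, phenotypes) so the whole pipeline can be exercised and
    validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    BiocGenerics,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    SummarizedExperiment
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
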