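Package: introTrace
Title: Forensics of Unintended Introgression and Somaclonal Variation in
    Transformant Rice Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and delimits donor-variety introgression segments in
    rice T-DNA insertion lines from multi-sample SNP calls, classifies their
    zygosity, and tracks them across selfing generations. Includes a forward
    simulator of the outcross/selfing/tissue-culture pedigree that produces
    VCF-structured genotype and read-count data with known haplotype truth,
    bulk-segregant SNP-index mapping of recessive traits from pooled allele
    counts, co-segregation filtering of candidate causal SNPs with a minimal
    coding-effect classifier, and an allele-sharing neighbor-joining
    phylogeny to verify donor versus recipient clustering.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    VariantAnnotation,
    rtracklayer,
    ape,
    phangorn,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Genetics, VariantAnnotation, Phylogenetics, Sequencing
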