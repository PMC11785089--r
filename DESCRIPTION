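Package: editomer
Title: A-to-I RNA Editome Construction and Four-Genotype Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to build A-to-I RNA editomes from per-sample RNA pileups
    and a germline exome variant set, and to compare them across genotypes.
    Candidate sites are A-to-G changes on the transcript strand (T-to-C on
    the reference minus strand), filtered by coverage and allele-fraction
    thresholds and purged of germline SNPs; per-genotype consensus editomes
    require a site (or gene) to be edited in every replicate. Sites are
    attributed to RNA elements (3'UTR, 5'UTR, CDS exon, intron, intergenic)
    and retroelement classes (LINE, SINE, DNA transposon, other), and
    genotypes are compared via counts tables, region distributions and
    four-set Venn partitions. Companion interferon-stimulated-gene (ISG)
    summaries cover log-CPM/FPKM normalisation, Welch tests with
    Benjamini-Hochberg correction, ISG fractions among differentially
    expressed genes, and an exact 2x2 test for ISG enrichment among uniquely
    edited sites. A synthetic-data generator plants known edits, SNPs and
    ISG expression tiers in a miniature genome so every stage is verifiable
    by parameter recovery, offline.
License: MIT
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
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    jsonlite
Config/testthat/edition: 3
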