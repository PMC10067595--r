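Package: bsaed
Title: Bulked-Segregant Association Scanning with the Euclidean-Distance
    Statistic
Version: 0.1.0
Authors@R:
    person("BSA-ED", "Maintainers", email = "maintainers@bsaed.example.org",
           role = c("aut", "cre"))
Description: A pipeline for bulked-segregant analysis (BSA-seq) of two
    phenotype-extreme DNA pools. Reads a two-sample VCF with per-pool
    allele depths, classifies per-pool genotypes from pooled read
    frequencies, applies MMAPPR-style pre-association site filters,
    computes the per-SNP Euclidean distance (ED) between the two pools'
    four-base frequency vectors, smooths ED^4 along each chromosome with
    tricube-weighted local polynomial regression, derives a median + 3 SD
    association threshold, extracts candidate regions and SNPs, performs
    hypergeometric gene-set enrichment with Benjamini-Hochberg
    correction, and validates markers against individual phenotypes with
    Pearson dosage tests. Includes a synthetic pooled-sequencing
    generator with a planted causal locus for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    VariantAnnotation,
    SummarizedExperiment,
    GenomeInfoDb,
    S4Vectors,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
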