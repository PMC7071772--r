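Package: dafscan
Title: Derived Allele Frequency Differentiation Scans and Haplotype Networks
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for scanning biallelic SNPs for strong allele-frequency
    differentiation between two population groups. Variants are polarized
    into ancestral and derived alleles (annotation first, primate-consensus
    fallback), pooled derived allele frequencies are compared with the
    absolute difference statistic (delta-DAF), and outliers are filtered by
    consequence severity. Companion population-genetic statistics include
    per-site FST (Hudson and Weir-Cockerham estimators), pairwise
    linkage-disequilibrium r-squared from phased haplotypes, LD-bounded
    window selection around a focal SNP, and median-joining haplotype
    networks with inferred median vectors. A Balding-Nichols simulator
    generates two-group datasets with known truth, including spiked
    high-differentiation loci, in the VCF/BED/TSV dialects the pipeline
    consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
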