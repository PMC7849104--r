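Package: moranprio
Title: Multilayered Post-GWAS SNP Prioritization with a Genomic Local
    Moran's Index
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Toolkit for prioritizing disease-associated SNPs beyond
    single-marker genome-wide association testing. Provides per-SNP
    logistic association and random-effects meta-analysis, a
    linkage-disequilibrium-weighted local spatial autocorrelation
    statistic (a genomic Local Moran's Index) over inverse-normal
    transformed odds ratios with its exclusion and top-fraction selection
    rules, approximate-Bayes-factor credible sets, median-rank
    permutation benchmarking against known hits, greedy LD clumping,
    overlap of prioritized variants with significant chromatin
    interaction calls, and a haplotype-block case-control simulator that
    generates reference panels, phenotypes and summary statistics for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    metafor,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
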