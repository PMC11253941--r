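Package: clinescan
Title: Genotype-Environment Association and Parallel Clines Across Transects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative genotype-environment adaptation analysis for replicated
    latitudinal transects: latent-factor association scans with genomic-inflation
    calibration and FDR-based outlier calling, SNP-to-gene candidate sets with a
    six-class functional-consequence scheme, cross-transect candidate overlap and
    allele-frequency-shift parallelism tests with permutation nulls, SNP-permutation
    GO enrichment with linkage-disequilibrium pruning, Weir-Cockerham F_ST and
    isolation-by-distance statistics, relatedness pruning, and a kinship-controlled
    mixed-model GWAS for body weight. Includes a synthetic multi-transect data
    generator (hierarchical Balding-Nichols drift, environmental clines, local
    linkage blocks, missingness, and a polygenic sex-affected phenotype) so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    jsonlite
Config/testthat/edition: 3
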