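Package: popgenscan
Title: Population Diversity, Differentiation and Selective-Sweep Scanning
    from Multi-Sample VCFs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for population-genomic analysis of diploid biallelic SNP
    data: VCF import/export and rule-based variant filtering (depth, call
    rate, missingness, minor allele frequency, exact Hardy-Weinberg test),
    per-population diversity statistics (polymorphism, heterozygosity, FIS),
    pairwise Weir-Cockerham FST and Reynolds' genetic distance, a
    sliding-window selective-sweep scan combining Z-transformed window FST
    with the log2 nucleotide-diversity ratio and Tajima's D confirmation,
    LD-decay curves with effective-population-size estimation from
    E(r^2) = 1/(1 + 4*Ne*c), and a Balding-Nichols genotype simulator with
    planted sweeps for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    vcfR,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
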