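Package: sweepscan
Title: Selective-Sweep Scans from Unphased Diploid Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome scans for recent selective sweeps in unphased diploid
    genotype data. Implements the G12 multisite-genotype homogeneity
    statistic and the H pairwise identity-tract scan, windowed
    Weir-Cockerham Fst between two cohorts, greedy outlier calling with
    iterative linkage masking, nearest-gene annotation with a
    permutation distance null, Gene Ontology biological-process
    enrichment with a permutation false-discovery estimate, and
    cross-population candidate comparison. Ships a founder-mosaic
    genotype simulator with injectable hard and soft sweeps so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
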