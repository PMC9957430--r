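Package: ladconnect
Title: Enhancer Connectivity and Chromatin States at Lamina-Associated Domains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for gene-regulatory interactions at
    lamina-associated domains (LADs): partitioning of the genome into
    constitutive LADs, variable LADs and inter-LADs from multi-timepoint LAD
    calls; annotation of euchromatic H3K4me1 regions inside constitutive LADs
    and contrasts of lamin enrichment between region classes; coverage-track
    arithmetic (log2 ChIP/input binning, TSS meta-profiles, expressed-gene
    filtering, relative expression); classification of enhancer-capture Hi-C
    baits and targets by LAD class and H3K4me1 status with per-bait
    connection-density statistics; chromatin-state segmentation with a
    multivariate Bernoulli hidden Markov model trained by Baum-Welch, with
    fold-enrichment of external annotations over states; FISH probe-probe and
    probe-to-periphery distance statistics; and a seeded synthetic-data
    generator emitting every input with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
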