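Package: aidsig
Title: AID Mutational Footprint Analysis in Somatic SNV Catalogs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to search leukemia whole-genome SNV catalogs for footprints
    of activation-induced cytidine deaminase (AID) mutagenesis. Builds
    96-channel trinucleotide-context mutation catalogs from VCF/TSV variant
    lists, refits fixed reference signature sets (e.g. COSMIC SBS) by
    non-negative least squares with cosine-similarity quality control,
    detects clustered mutations and kataegis by inter-mutation distance,
    tests per-gene enrichment of mutations in AID target motifs (RC>NY,
    WRC>NY, WRC>N) with Fisher's exact test and Benjamini-Hochberg
    correction, and simulates multi-sample SNV cohorts with known signature
    mixtures, injected kataegis and motif-biased gene mutations for
    ground-truth validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
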