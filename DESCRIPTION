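Package: spongeworks
Title: Competing Endogenous RNA Network Inference from RNA-Seq Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated pipeline for inferring miRNA-sponge (competing
    endogenous RNA) networks from matched long-RNA and small-RNA sequencing
    of a two-condition design (tumour versus matched control). Implements
    small-RNA read cleaning, TPM/FPKM quantification with gene-level
    summation, known-miRNA tag assignment, the Audic-Claverie exact test for
    digital expression counts, a multi-step lncRNA classification cascade
    (class code, length, known-lncRNA matching, coding potential),
    canonical miRNA seed-site (MRE) prediction with predictor combination,
    cis and antisense lncRNA target assignment, hypergeometric term
    enrichment, and assembly of the miRNA-centred tripartite sponge
    network. A synthetic-data generator implants a known sponge network
    into simulated transcriptomes and counts so that every stage of the
    pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
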