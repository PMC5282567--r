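Package: cernet
Title: Competing Endogenous RNA Network Inference and Biomarker
    Evaluation for Case-Control Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrative pipeline for competing endogenous RNA (ceRNA)
    analysis of case-control transcriptome profiles, motivated by studies of
    mitochondrial myopathy (MELAS) muscle and serum.  Provides differential
    expression calling on microarray signal and FPKM matrices with LOWESS
    normalisation, canonical miRNA seed-site target scanning (6mer, 7mer-A1,
    7mer-m8, 8mer), cis/trans lncRNA-mRNA pairing, assembly of
    anticorrelation-constrained miRNA-mRNA-lncRNA and lncRNA-miRNA-mRNA
    networks with triad summaries and Cytoscape export, hypergeometric
    gene-set over-representation with Benjamini-Hochberg correction and rich
    factors, and qRT-PCR biomarker evaluation (2^-ddCt relative
    quantification, DeLong ROC analysis with Youden cutoffs, rank
    correlations with clinical covariates).  A seeded synthetic-data
    generator emulates the pooled case-control study design with planted
    differential expression, seed-match ceRNA triads, Ct tables and a
    binormal serum biomarker, enabling end-to-end parameter-recovery tests
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    fgsea,
    igraph,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
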