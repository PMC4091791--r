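Package: transmed
Title: Cis and Trans eQTL Mapping with Permutation FDR and Causal
    Mediation Calling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Spearman rank association mapping of SNP and copy-number
    dosages to probe-level gene expression in cis (window around the
    transcription start site) and in trans, with gene-based and
    genome-wide permutation false-discovery-rate control, conditional
    regression for independent cis-eQTLs, heritability partitioning,
    Storey pi1 sharing and replication analysis, matched-variant
    enrichment testing, copy-number artifact filters, and consensus
    causal calling of variant/cis-gene/trans-gene triplets by Gaussian
    Bayesian-network AIC selection and a causal inference test. Includes
    a seeded synthetic cohort generator with planted cis effects,
    mediation chains and ground truth for recovery experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, tools, limma
Suggests: testthat (>= 3.0.0), jsonlite, optparse, vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
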