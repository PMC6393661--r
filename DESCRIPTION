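Package: lnctrans
Title: Inference of lncRNA-Mediated Trans-Regulatory Networks from
    Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds ranked lncRNA-TF-target gene trans-regulatory networks
    from case/control FPKM expression matrices. Identifies differentially
    expressed mRNAs and lncRNAs, computes lncRNA-mRNA Pearson co-expression
    with exact small-sample significance, annotates lncRNAs by hypergeometric
    over-representation of their co-expressed genes in gene-set collections,
    scores lncRNA-TF pairs against TF regulons, assembles the triad network,
    and exports it in SIF/GraphML for network-visualization tools. Includes a
    latent-activity synthetic expression simulator with planted ground truth
    for calibration and parameter-recovery testing, an IUPAC consensus motif
    scanner for binding-site evidence, and 2^-ddCt qPCR quantification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    xml2,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
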