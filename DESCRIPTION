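Package: ceRNAnet
Title: Inference of Competing Endogenous RNA (lncRNA-mRNA) Networks from
    Shared miRNA Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds significance-filtered lncRNA-mRNA competing endogenous RNA
    (ceRNA) networks from candidate lncRNA-miRNA and miRNA-mRNA interaction
    tables and two-group expression profiles. Provides probe re-annotation
    filtering, two-group differential expression with fold-change and FDR
    thresholds, assembly of a tripartite background network, a hypergeometric
    shared-miRNA test for lncRNA-mRNA pairs, centrality-based key-lncRNA
    selection with a scale-free (power-law) topology check, MCODE
    seed-expansion module detection with haircut and fluff post-processing,
    gene-set over-representation analysis against GMT collections, per-lncRNA
    ceRNA sub-network extraction, and a synthetic-data generator with planted
    ceRNA pairs, hub lncRNAs and differential expression for end-to-end
    validation of the whole workflow.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    limma,
    fgsea,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
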