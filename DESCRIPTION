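Package: stagenet
Title: Stage-Specific Transcription Factor-lncRNA Regulatory Network Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Construction and analysis of stage-specific bipartite
    transcription factor (TF) to long non-coding RNA (lncRNA) regulatory
    networks from binding evidence and co-expression. Candidate TF-lncRNA
    pairs are derived by mapping conserved binding sites and ChIP-seq peaks
    to promoter windows, filtered per tumour stage by positive Pearson
    correlation under FDR control, scored for cross-stage activity and
    stage specificity, mined for maximal bicliques, and evaluated for
    prognostic value with Cox proportional-hazards risk scores,
    Kaplan-Meier curves and log-rank tests. A synthetic-cohort generator
    with planted co-expression and survival structure supports end-to-end
    testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    igraph,
    survival,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
biocViews: NetworkInference, GraphAndNetwork, Survival, GeneRegulation,
    Transcriptomics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'methods-accessors.R'
    'bicliques.R'
    'binding-evidence.R'
    'dynamics.R'
    'pipeline.R'
    'stage-networks.R'
    'survival.R'
    'synthetic-cohort.R'
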