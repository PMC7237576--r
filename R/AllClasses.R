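#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

#' StageCohort: expression plus staged clinical annotation
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding a
#' genes-by-samples expression matrix (assay \code{"expr"}, non-negative
#' values on an RPKM-like scale), a per-sample tumour stage label and,
#' optionally, survival and clinical covariates (\code{time} in months,
#' \code{event} 0/1, \code{age}, \code{grade}). Synthetic cohorts carry the
#' planted ground truth (edges and clique) in \code{metadata(x)$truth} so
#' recovery can be tested.
#'
#' @slot ... see \linkS4class{SummarizedExperiment}.
#' @seealso \code{\link{simulateCohort}}, \code{\link{sampleStage}}
#' @export
setClass("StageCohort", contains = "SummarizedExperiment")

setValidity("StageCohort", function(object) {
    msg <- NULL
    if (!"expr" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'expr' is required")
    else if (any(SummarizedExperiment::assay(object, "expr") < 0))
        msg <- c(msg, "expression values must be non-negative")
    cd <- colData(object)
    if (!"stage" %in% colnames(cd))
        msg <- c(msg, "colData must contain a 'stage' column")
    if ("time" %in% colnames(cd) && any(cd$time <= 0))
        msg <- c(msg, "survival times must be strictly positive")
    if ("event" %in% colnames(cd) && !all(cd$event %in% c(0L, 1L)))
        msg <- c(msg, "event indicator must be 0/1")
    if (is.null(msg)) TRUE else msg
})

#' StageNetwork: one stage's bipartite TF-lncRNA network
#'
#' Edges are TF-lncRNA pairs that passed the positive-correlation plus FDR
#' filter within one tumour stage. The graph is bipartite by construction:
#' TFs only connect to lncRNAs. Isolated nodes are not part of the network.
#'
#' @slot stage single stage label.
#' @slot edges data.frame with columns \code{tf}, \code{lnc}, \code{r},
#'   \code{p}, \code{q} (Pearson coefficient, two-sided p, BH-adjusted q);
#'   retained rows satisfy \code{r > 0} and \code{q < alpha}.
#' @slot alpha FDR threshold used at construction.
#' @slot nTested number of candidate edges tested (the FDR family size).
#' @export
setClass("StageNetwork",
    representation(stage = "character", edges = "data.frame",
                   alpha = "numeric", nTested = "integer"))

setValidity("StageNetwork", function(object) {
    e <- object@edges
    need <- c("tf", "lnc", "r", "p", "q")
    if (!all(need %in% colnames(e)))
        return(paste("edges must have columns", paste(need, collapse = ", ")))
    if (nrow(e) && any(e$r <= 0))
        return("all retained edges must have r > 0")
    if (nrow(e) && any(e$q < e$p - 1e-12))
        return("adjusted q must be >= p")
    if (anyDuplicated(paste(e$tf, e$lnc)))
        return("duplicate (tf, lnc) edges")
    TRUE
})

#' ActivityProfiles: cross-stage edge activity and specificity
#'
#' For every edge significant in at least one stage network, the raw
#' per-stage Pearson coefficients, their per-stage z-normalised min-shifted
#' activity scores, the stage-specificity score in [0, 1] and (optionally)
#' a K-means activity group.
#'
#' @slot tf,lnc character vectors identifying each edge (rows).
#' @slot raw edges-by-stages matrix of Pearson coefficients.
#' @slot activity edges-by-stages matrix; per stage, z-scored over edges
#'   then shifted so the stage minimum is exactly 0.
#' @slot specificity numeric in [0, 1]; NA for all-zero profiles.
#' @slot group integer cluster labels (NA before clustering), labelled in
#'   descending cluster size.
#' @export
setClass("ActivityProfiles",
    representation(tf = "character", lnc = "character", raw = "matrix",
                   activity = "matrix", specificity = "numeric",
                   group = "integer"))

setValidity("ActivityProfiles", function(object) {
    n <- length(object@tf)
    if (length(object@lnc) != n || nrow(object@raw) != n ||
        nrow(object@activity) != n || length(object@specificity) != n ||
        length(object@group) != n)
        return("row dimensions disagree")
    if (n && any(object@activity < -1e-9))
        return("activity scores must be non-negative after min-shift")
    ok <- !is.na(object@specificity)
    if (any(object@specificity[ok] < -1e-9 | object@specificity[ok] > 1 + 1e-9))
        return("specificity scores must lie in [0, 1]")
    TRUE
})

#' BicliqueSet: maximal TF-lncRNA bicliques with scores
#'
#' Each element is a maximal complete bipartite subgraph of the source
#' network: every TF in \code{tfs} regulates every lncRNA in \code{lncs},
#' and no node can be added without breaking completeness.
#'
#' @slot cliques list of \code{list(tfs=, lncs=)} with sorted members.
#' @slot stats data.frame: \code{id}, \code{n_tf}, \code{n_lnc},
#'   \code{size}, and after scoring \code{mean_specificity}, \code{rank},
#'   \code{cluster}.
#' @export
setClass("BicliqueSet",
    representation(cliques = "list", stats = "data.frame"))

setValidity("BicliqueSet", function(object) {
    if (length(object@cliques) != nrow(object@stats))
        return("stats rows must match clique count")
    TRUE
})

#' RiskModel: clique-based proportional-hazards risk signature
#'
#' Per-node univariate Cox coefficients fitted on a training cohort, the
#' linear risk score they induce, and the training-median cutoff used to
#' stratify any cohort into high/low risk. The cutoff is fixed at training
#' time and is never recomputed on test data.
#'
#' @slot nodes clique member gene ids.
#' @slot coefficients named per-node univariate Cox log-hazard ratios.
#' @slot cutoff training-median risk score.
#' @slot trainExpr nodes-by-training-samples expression, kept so that a
#'   reduced model (validation cohorts missing some nodes) can rescale its
#'   cutoff to the available-node training median.
#' @slot table per-node data.frame (coef, HR, CI, p).
#' @export
setClass("RiskModel",
    representation(nodes = "character", coefficients = "numeric",
                   cutoff = "numeric", trainExpr = "matrix",
                   table = "data.frame"))

setValidity("RiskModel", function(object) {
    if (!all(names(object@coefficients) == object@nodes))
        return("coefficient names must equal nodes")
    if (!all(rownames(object@trainExpr) == object@nodes))
        return("trainExpr rows must equal nodes")
    TRUE
})
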