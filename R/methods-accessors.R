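#' @include AllGenerics.R
NULL

#' @rdname stagenet-accessors
#' @export
setMethod("exprMatrix", "StageCohort", function(x, ...)
    SummarizedExperiment::assay(x, "expr"))

#' @rdname stagenet-accessors
#' @export
setMethod("sampleStage", "StageCohort", function(x, ...) {
    s <- as.character(colData(x)$stage)
    names(s) <- colnames(x)
    s
})

#' @rdname stagenet-accessors
#' @export
setMethod("clinicalData", "StageCohort", function(x, ...) {
    df <- as.data.frame(colData(x))
    df$sample <- colnames(x)
    df[, c("sample", setdiff(colnames(df), "sample")), drop = FALSE]
})

#' @rdname stagenet-accessors
#' @export
setMethod("cohortTruth", "StageCohort", function(x, ...) metadata(x)$truth)

#' @rdname stagenet-accessors
#' @export
setMethod("stageLabel", "StageNetwork", function(x, ...) x@stage)

#' @rdname stagenet-accessors
#' @export
setMethod("networkEdges", "StageNetwork", function(x, ...) x@edges)

#' @rdname stagenet-accessors
#' @export
setMethod("tfNodes", "StageNetwork", function(x, ...)
    sort(unique(x@edges$tf)))

#' @rdname stagenet-accessors
#' @export
setMethod("lncNodes", "StageNetwork", function(x, ...)
    sort(unique(x@edges$lnc)))

#' @rdname stagenet-accessors
#' @export
setMethod("activityMatrix", "ActivityProfiles", function(x, ...) {
    m <- x@activity
    rownames(m) <- edgeIds(x@tf, x@lnc)
    m
})

#' @rdname stagenet-accessors
#' @export
setMethod("rawCorrelations", "ActivityProfiles", function(x, ...) {
    m <- x@raw
    rownames(m) <- edgeIds(x@tf, x@lnc)
    m
})

#' @rdname stagenet-accessors
#' @export
setMethod("specificity", "ActivityProfiles", function(x, ...) {
    s <- x@specificity
    names(s) <- edgeIds(x@tf, x@lnc)
    s
})

#' @rdname stagenet-accessors
#' @export
setMethod("activityGroups", "ActivityProfiles", function(x, ...) {
    g <- x@group
    names(g) <- edgeIds(x@tf, x@lnc)
    g
})

#' @rdname stagenet-accessors
#' @export
setMethod("cliques", "BicliqueSet", function(x, ...) x@cliques)

#' @rdname stagenet-accessors
#' @export
setMethod("cliqueStats", "BicliqueSet", function(x, ...) x@stats)

#' @rdname stagenet-accessors
#' @export
setMethod("riskCoefficients", "RiskModel", function(x, ...) x@coefficients)

#' @rdname stagenet-accessors
#' @export
setMethod("riskCutoff", "RiskModel", function(x, ...) x@cutoff)

#' Canonical edge identifier
#'
#' @param tf,lnc character vectors of node ids.
#' @return character vector "tf|lnc".
#' @export
edgeIds <- function(tf, lnc) paste(tf, lnc, sep = "|")

setMethod("show", "StageCohort", function(object) {
    st <- table(colData(object)$stage)
    cat("StageCohort:", nrow(object), "genes x", ncol(object), "samples\n")
    cat("  stages:", paste(names(st), st, sep = "=", collapse = ", "), "\n")
    cat("  clinical:", if ("time" %in% colnames(colData(object)))
        "survival present" else "none", "\n")
    if (!is.null(metadata(object)$truth))
        cat("  planted truth:",
            nrow(metadata(object)$truth$edges), "edges,",
            length(metadata(object)$truth$clique$nodes), "clique nodes\n")
})

setMethod("show", "StageNetwork", function(object) {
    cat("StageNetwork [stage ", object@stage, "]: ",
        nrow(object@edges), " edges, ",
        length(tfNodes(object)), " TFs, ", length(lncNodes(object)),
        " lncRNAs (", object@nTested, " candidates tested, alpha=",
        object@alpha, ")\n", sep = "")
})

setMethod("show", "ActivityProfiles", function(object) {
    cat("ActivityProfiles:", length(object@tf), "edges x",
        ncol(object@raw), "stages\n")
    ok <- !is.na(object@specificity)
    if (any(ok))
        cat("  mean specificity:",
            round(mean(object@specificity[ok]), 3), "\n")
    if (any(!is.na(object@group)))
        cat("  activity groups:", length(unique(stats::na.omit(object@group))), "\n")
})

setMethod("show", "BicliqueSet", function(object) {
    cat("BicliqueSet:", length(object@cliques), "maximal bicliques\n")
    if (length(object@cliques)) {
        sz <- object@stats$size
        cat("  node count range:", min(sz), "-", max(sz),
            " mean:", round(mean(sz), 2), "\n")
        if ("mean_specificity" %in% colnames(object@stats) &&
            any(!is.na(object@stats$mean_specificity)))
            cat("  scored; top mean specificity:",
                round(max(object@stats$mean_specificity, na.rm = TRUE), 3), "\n")
    }
})

setMethod("show", "RiskModel", function(object) {
    cat("RiskModel:", length(object@nodes), "nodes, cutoff",
        signif(object@cutoff, 4), "\n")
    print(object@table, digits = 3)
})
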