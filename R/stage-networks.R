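#' @include methods-accessors.R
NULL

#' Pearson correlation with two-sided t-test p-value
#'
#' Thin wrapper over \code{stats::cor.test} returning the coefficient and
#' the two-sided p-value from the t distribution with n - 2 df. Zero
#' variance in either vector yields \code{r = NA} (undefined correlation)
#' rather than an error so callers can drop such edges with a warning.
#'
#' @param x,y equal-length numeric vectors, n >= 3.
#' @return list with elements \code{r} and \code{p}.
#' @export
pearsonTest <- function(x, y) {
    if (length(x) != length(y) || length(x) < 3)
        stop("need equal-length vectors with n >= 3")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        return(list(r = NA_real_, p = NA_real_))
    ct <- stats::cor.test(x, y, method = "pearson")
    list(r = unname(ct$estimate), p = ct$p.value)
}

# RPKM-like values are strongly right-skewed; Pearson on the raw scale is
# outlier-driven and its t-test anti-conservative, so co-expression is
# computed on log2(x + 1) by default.
.prepExpr <- function(expr, transform = c("log2", "none")) {
    transform <- match.arg(transform)
    if (transform == "log2") log2(expr + 1) else expr
}

# Vectorised per-edge Pearson r and two-sided p for candidate pairs.
# Equivalent to cor.test per edge; t = r*sqrt((n-2)/(1-r^2)), p from t_{n-2}.
.edgeCorrelations <- function(candidates, expr) {
    n <- ncol(expr)
    tfs <- unique(candidates$tf)
    lncs <- unique(candidates$lnc)
    cc <- suppressWarnings(
        stats::cor(t(expr[tfs, , drop = FALSE]),
                   t(expr[lncs, , drop = FALSE])))
    r <- cc[cbind(match(candidates$tf, tfs), match(candidates$lnc, lncs))]
    r[abs(r) >= 1 - 1e-15 & !is.na(r)] <-
        sign(r[abs(r) >= 1 - 1e-15 & !is.na(r)]) * (1 - 1e-15)
    tt <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    data.frame(tf = candidates$tf, lnc = candidates$lnc, r = r, p = p)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (delegates to \code{stats::p.adjust}).
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted q-values, capped at 1.
#' @export
bhAdjust <- function(p) {
    if (any(p < 0 | p > 1, na.rm = TRUE))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Build one stage-specific TF-lncRNA network
#'
#' For every candidate edge, computes the Pearson correlation between TF
#' and lncRNA expression over the stage's samples and keeps edges with
#' positive correlation and BH-adjusted FDR below \code{alpha}. The FDR
#' family is all candidate edges tested within the stage. Candidate edges
#' touching a zero-variance gene are dropped with a warning.
#'
#' @param candidates data.frame (\code{tf}, \code{lnc}).
#' @param expr genes-by-samples expression matrix covering all candidate
#'   nodes.
#' @param stageMap named character vector sample -> stage.
#' @param stage stage label to build (>= 3 samples required).
#' @param alpha FDR threshold (default 0.05).
#' @param transform expression transform applied before correlation:
#'   \code{"log2"} (default, \code{log2(x + 1)} — standard for skewed
#'   RPKM-like values and keeps the correlation t-test calibrated) or
#'   \code{"none"}.
#' @return a \linkS4class{StageNetwork}.
#' @export
buildStageNetwork <- function(candidates, expr, stageMap, stage,
                              alpha = 0.05,
                              transform = c("log2", "none")) {
    expr <- .prepExpr(expr, transform)
    samples <- names(stageMap)[stageMap == stage]
    if (!length(samples))
        stop("stage '", stage, "' absent from the sample map")
    if (length(samples) < 3)
        stop("stage '", stage, "' has fewer than 3 samples")
    miss <- setdiff(unique(c(candidates$tf, candidates$lnc)),
                    rownames(expr))
    if (length(miss))
        stop("candidate nodes missing from expression matrix: ",
             paste(utils::head(miss, 5), collapse = ", "))
    if (!nrow(candidates))
        return(methods::new("StageNetwork", stage = stage,
                            edges = data.frame(tf = character(),
                                               lnc = character(),
                                               r = numeric(), p = numeric(),
                                               q = numeric()),
                            alpha = alpha, nTested = 0L))
    es <- .edgeCorrelations(candidates, expr[, samples, drop = FALSE])
    bad <- is.na(es$r)
    if (any(bad)) {
        warning(sum(bad), " candidate edge(s) dropped in stage ", stage,
                ": undefined correlation (zero variance)")
        es <- es[!bad, , drop = FALSE]
    }
    es$q <- bhAdjust(es$p)
    keep <- es$r > 0 & es$q < alpha
    edges <- es[keep, , drop = FALSE]
    edges <- edges[order(edges$tf, edges$lnc), , drop = FALSE]
    rownames(edges) <- NULL
    methods::new("StageNetwork", stage = stage, edges = edges,
                 alpha = alpha, nTested = nrow(es))
}

#' Build all stage networks of a cohort
#'
#' @param candidates data.frame (\code{tf}, \code{lnc}).
#' @param cohort a \linkS4class{StageCohort}.
#' @param alpha FDR threshold.
#' @param transform see \code{\link{buildStageNetwork}}.
#' @return named list of \linkS4class{StageNetwork}, one per stage.
#' @export
buildStageNetworks <- function(candidates, cohort, alpha = 0.05,
                               transform = c("log2", "none")) {
    sm <- sampleStage(cohort)
    stages <- unique(sm)
    nets <- lapply(stages, function(s)
        buildStageNetwork(candidates, exprMatrix(cohort), sm, s,
                          alpha = alpha, transform = transform))
    names(nets) <- stages
    nets
}

# Undirected igraph from a StageNetwork (or tf/lnc edge frame); nodes keep
# a 'kind' attribute so bipartiteness survives the conversion.
.asIgraph <- function(x) {
    e <- if (methods::is(x, "StageNetwork")) networkEdges(x) else x
    tfs <- sort(unique(e$tf))
    lncs <- sort(unique(e$lnc))
    if (length(intersect(tfs, lncs)))
        stop("graph is not bipartite: shared node ids across parts")
    g <- igraph::graph_from_data_frame(
        e[, c("tf", "lnc")], directed = FALSE,
        vertices = data.frame(name = c(tfs, lncs),
                              kind = rep(c("tf", "lnc"),
                                         c(length(tfs), length(lncs)))))
    g
}

#' Node degree of a stage network
#'
#' @param network a \linkS4class{StageNetwork} (or data.frame of
#'   \code{tf}/\code{lnc} edges).
#' @return named integer vector, node -> neighbour count.
#' @export
nodeDegree <- function(network) {
    g <- .asIgraph(network)
    d <- igraph::degree(g)
    d[order(names(d))]
}

#' Topological coefficient of each node
#'
#' For node n with degree e, the topological coefficient is
#' \code{mean_m J(n, m) / e} where m ranges over every node sharing at
#' least one neighbour with n, and J(n, m) is the number of neighbours
#' shared by n and m, plus one when n and m are directly linked (the
#' NetworkAnalyzer convention; set \code{countAdjacent = FALSE} for the
#' plain shared-neighbour count). Nodes with no such partner (including
#' isolated nodes) get \code{NA}.
#'
#' @param network a \linkS4class{StageNetwork} or edge data.frame.
#' @param countAdjacent add 1 to J(n, m) for adjacent pairs (default TRUE).
#' @return named numeric vector, node -> coefficient.
#' @export
topologicalCoefficient <- function(network, countAdjacent = TRUE) {
    g <- .asIgraph(network)
    A <- as.matrix(igraph::as_adjacency_matrix(g))
    sharedN <- A %*% A           # shared-neighbour counts
    J <- if (countAdjacent) sharedN + A else sharedN
    deg <- rowSums(A)
    n <- nrow(A)
    out <- rep(NA_real_, n)
    names(out) <- rownames(A)
    for (i in seq_len(n)) {
        partners <- which(sharedN[i, ] > 0 & seq_len(n) != i)
        if (length(partners) && deg[i] > 0)
            out[i] <- mean(J[i, partners]) / deg[i]
    }
    out[order(names(out))]
}

#' Betweenness centrality, pair-normalised
#'
#' Shortest-path betweenness on the undirected bipartite graph, divided by
#' \code{(N - 1)(N - 2) / 2} so values lie in [0, 1].
#'
#' @param network a \linkS4class{StageNetwork} or edge data.frame.
#' @return named numeric vector in [0, 1].
#' @export
betweennessCentrality <- function(network) {
    g <- .asIgraph(network)
    n <- igraph::vcount(g)
    b <- igraph::betweenness(g, directed = FALSE)
    if (n > 2) b <- b / ((n - 1) * (n - 2) / 2)
    b[order(names(b))]
}

#' Overlap (Venn) counts of TFs, lncRNAs and edges across networks
#'
#' Every element of each class is assigned to the region named by the
#' networks containing it ("II", "II&III", ...); regions partition the
#' union.
#'
#' @param networks named list of >= 2 \linkS4class{StageNetwork}s.
#' @return list with elements \code{tfs}, \code{lncs}, \code{edges}: named
#'   integer vectors of region counts.
#' @export
networkOverlap <- function(networks) {
    if (length(networks) < 2) stop("need at least two networks")
    labs <- names(networks)
    regionCounts <- function(sets) {
        all <- unique(unlist(sets))
        if (!length(all)) return(stats::setNames(integer(0), character(0)))
        sig <- vapply(all, function(el)
            paste(labs[vapply(sets, function(s) el %in% s, logical(1))],
                  collapse = "&"), character(1))
        table(sig) |> c()
    }
    list(
        tfs = regionCounts(lapply(networks, tfNodes)),
        lncs = regionCounts(lapply(networks, lncNodes)),
        edges = regionCounts(lapply(networks, function(n) {
            e <- networkEdges(n)
            edgeIds(e$tf, e$lnc)
        })))
}
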