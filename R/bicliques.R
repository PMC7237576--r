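#' @include methods-accessors.R
NULL

# Closure-based enumeration of maximal bicliques over the TF side.
# Maximal bicliques of a bipartite graph are in bijection with closed TF
# sets (A closed iff A = {t : N(t) >= commonNeighbourhood(A)}); closed sets
# are enumerated depth-first with prefix-preserving closure extension so
# each is visited exactly once, pruning branches whose common lncRNA
# neighbourhood has already fallen below the size floor.
.maximalBicliques <- function(adj, minTfs, minLncs) {
    nT <- length(adj)
    out <- vector("list", 0L)
    if (!nT) return(out)
    universe <- sort(unique(unlist(adj)))
    rec <- function(A, C, start) {
        for (i in start:nT) {
            if (i %in% A) next
            Ci <- intersect(C, adj[[i]])
            if (length(Ci) < minLncs) next
            A2 <- which(vapply(adj, function(N) all(Ci %in% N), logical(1)))
            if (any(A2 < i & !(A2 %in% c(A, i)))) next  # seen via a smaller prefix
            if (length(A2) >= minTfs)
                out[[length(out) + 1L]] <<- list(tfs = A2, lncs = Ci)
            if (i < nT) rec(A2, Ci, i + 1L)
        }
    }
    rec(integer(0), universe, 1L)
    out
}

#' Enumerate maximal TF-lncRNA bicliques
#'
#' Finds every maximal complete bipartite subgraph (every TF connected to
#' every lncRNA, no node addable) of the network meeting the size floor.
#' The result is independent of node iteration order: cliques are returned
#' in a canonical order (descending node count, then id).
#'
#' @param network a \linkS4class{StageNetwork} or data.frame of
#'   \code{tf}/\code{lnc} edges (e.g. the union of several stage networks;
#'   see \code{\link{unionNetwork}}).
#' @param minTfs,minLncs minimum part sizes (defaults 2 and 2, so a clique
#'   has at least 4 nodes).
#' @return a \linkS4class{BicliqueSet}.
#' @examples
#' k33 <- expand.grid(tf = paste0("TF", 1:3), lnc = paste0("LNC", 1:3),
#'                    stringsAsFactors = FALSE)
#' length(cliques(enumerateBicliques(k33)))  # 1
#' @export
enumerateBicliques <- function(network, minTfs = 2, minLncs = 2) {
    e <- if (methods::is(network, "StageNetwork")) networkEdges(network)
         else as.data.frame(network)
    e <- unique(e[, c("tf", "lnc")])
    if (length(intersect(e$tf, e$lnc)))
        stop("graph is not bipartite: shared node ids across parts")
    tfs <- sort(unique(e$tf))
    lncs <- sort(unique(e$lnc))
    adj <- lapply(tfs, function(t) sort(match(e$lnc[e$tf == t], lncs)))
    names(adj) <- tfs
    found <- .maximalBicliques(adj, minTfs, minLncs)
    cl <- lapply(found, function(b)
        list(tfs = tfs[b$tfs], lncs = sort(lncs[b$lncs])))
    ids <- vapply(cl, function(b)
        paste(paste(b$tfs, collapse = "+"), paste(b$lncs, collapse = "+"),
              sep = "|"), character(1))
    sizes <- vapply(cl, function(b) length(b$tfs) + length(b$lncs),
                    numeric(1))
    o <- order(-sizes, ids)
    cl <- cl[o]
    stats <- data.frame(
        id = ids[o],
        n_tf = vapply(cl, function(b) length(b$tfs), numeric(1)),
        n_lnc = vapply(cl, function(b) length(b$lncs), numeric(1)),
        size = sizes[o])
    rownames(stats) <- NULL
    methods::new("BicliqueSet", cliques = cl, stats = stats)
}

#' Union graph of several stage networks
#'
#' Edges significant in at least one stage; the default universe for
#' cross-stage biclique mining.
#'
#' @param networks list of \linkS4class{StageNetwork}s.
#' @return data.frame (\code{tf}, \code{lnc}).
#' @export
unionNetwork <- function(networks) {
    e <- unique(do.call(rbind, lapply(networks, function(n)
        networkEdges(n)[, c("tf", "lnc")])))
    e <- e[order(e$tf, e$lnc), , drop = FALSE]
    rownames(e) <- NULL
    e
}

#' Score bicliques by mean edge specificity and keep the top k
#'
#' Attaches to each biclique the mean stage-specificity score over all its
#' TF-lncRNA edges, sorts in descending mean (ties broken by descending
#' size, then lexicographic id — a documented, stable order) and returns
#' the first \code{topK}.
#'
#' @param bicliqueSet a \linkS4class{BicliqueSet}.
#' @param edgeSpecificities named numeric vector, \code{"tf|lnc"} ->
#'   specificity (as from \code{specificity(profiles)}); every clique edge
#'   must be present and non-NA.
#' @param topK cliques to retain (default 50).
#' @return a \linkS4class{BicliqueSet} with \code{mean_specificity} and
#'   \code{rank} columns.
#' @export
rankBicliques <- function(bicliqueSet, edgeSpecificities, topK = 50) {
    cl <- cliques(bicliqueSet)
    ms <- vapply(cl, function(b) {
        keys <- as.vector(outer(b$tfs, b$lncs, edgeIds))
        v <- edgeSpecificities[keys]
        if (any(is.na(v)))
            stop("missing specificity for clique edge(s): ",
                 paste(utils::head(keys[is.na(v)], 3), collapse = ", "))
        mean(v)
    }, numeric(1))
    st <- cliqueStats(bicliqueSet)
    st$mean_specificity <- ms
    o <- order(-st$mean_specificity, -st$size, st$id)
    keep <- utils::head(o, topK)
    st <- st[keep, , drop = FALSE]
    st$rank <- seq_len(nrow(st))
    rownames(st) <- NULL
    methods::new("BicliqueSet", cliques = cl[keep], stats = st)
}

#' Jaccard similarity of two node sets
#'
#' Size of the intersection over size of the union.
#'
#' @param x,y character vectors (duplicates ignored); both empty is an
#'   error.
#' @return coefficient in [0, 1].
#' @export
jaccardIndex <- function(x, y) {
    x <- unique(x); y <- unique(y)
    u <- union(x, y)
    if (!length(u)) stop("Jaccard undefined for two empty sets")
    length(intersect(x, y)) / length(u)
}

#' Pairwise Jaccard similarity of bicliques
#'
#' Similarity between two cliques is the Jaccard coefficient of their
#' combined node sets (TFs and lncRNAs pooled).
#'
#' @param bicliqueSet a \linkS4class{BicliqueSet}.
#' @return symmetric matrix with unit diagonal.
#' @export
cliqueSimilarity <- function(bicliqueSet) {
    cl <- cliques(bicliqueSet)
    nodes <- lapply(cl, function(b) c(b$tfs, b$lncs))
    n <- length(nodes)
    m <- diag(1, n)
    if (n > 1)
        for (i in seq_len(n - 1)) for (j in (i + 1):n)
            m[i, j] <- m[j, i] <- jaccardIndex(nodes[[i]], nodes[[j]])
    dimnames(m) <- list(cliqueStats(bicliqueSet)$id,
                        cliqueStats(bicliqueSet)$id)
    m
}

#' Cluster bicliques from their similarity matrix
#'
#' Average-linkage hierarchical clustering on the distance 1 - J, cut into
#' \code{nClusters} groups. Deterministic.
#'
#' @param similarity symmetric Jaccard matrix (\code{\link{cliqueSimilarity}}).
#' @param nClusters group count (default 5); must not exceed the clique
#'   count.
#' @return integer cluster labels, named by clique id.
#' @export
clusterCliques <- function(similarity, nClusters = 5) {
    if (nClusters > nrow(similarity))
        stop("nClusters exceeds the number of cliques")
    if (nrow(similarity) == 1)
        return(stats::setNames(1L, rownames(similarity)))
    hc <- stats::hclust(stats::as.dist(1 - similarity), method = "average")
    stats::cutree(hc, k = nClusters)
}
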