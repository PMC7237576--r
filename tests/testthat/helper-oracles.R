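# Independent brute-force oracles used only by tests. They deliberately
# share no code with the package implementations.

# Random bipartite edge list, nodes named "t*"/"l*"
randomBipartite <- function(nTf, nLnc, p, seed) {
    set.seed(seed)
    g <- expand.grid(tf = paste0("t", seq_len(nTf)),
                     lnc = paste0("l", seq_len(nLnc)),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    g[runif(nrow(g)) < p, , drop = FALSE]
}

# Maximal bicliques by exhaustive enumeration over all TF subsets:
# for each subset take its common lncRNA neighbourhood, close on the TF
# side, and keep closed pairs meeting the size floor.
bruteForceBicliques <- function(edges, minTfs = 2, minLncs = 2) {
    tfs <- sort(unique(edges$tf))
    adj <- lapply(tfs, function(t) sort(unique(edges$lnc[edges$tf == t])))
    names(adj) <- tfs
    seen <- character(0)
    out <- list()
    for (k in seq_len(2^length(tfs) - 1)) {
        A <- tfs[bitwAnd(bitwShiftR(k, seq_along(tfs) - 1L), 1L) == 1L]
        B <- Reduce(intersect, adj[A])
        if (length(B) < minLncs) next
        A2 <- tfs[vapply(adj, function(N) all(B %in% N), logical(1))]
        if (length(A2) < minTfs) next
        id <- paste(paste(sort(A2), collapse = "+"),
                    paste(sort(B), collapse = "+"), sep = "|")
        if (id %in% seen) next
        seen <- c(seen, id)
        out[[length(out) + 1L]] <- list(tfs = sort(A2), lncs = sort(B))
    }
    out
}

cliqueIdSet <- function(cliqueList)
    sort(vapply(cliqueList, function(b)
        paste(paste(sort(b$tfs), collapse = "+"),
              paste(sort(b$lncs), collapse = "+"), sep = "|"), character(1)))

# Completeness + maximality check straight from the definition
isMaximalBiclique <- function(edges, tfsIn, lncsIn) {
    key <- paste(edges$tf, edges$lnc)
    has <- function(t, l) paste(t, l) %in% key
    complete <- all(outer(tfsIn, lncsIn, Vectorize(has)))
    if (!complete) return(FALSE)
    extT <- setdiff(unique(edges$tf), tfsIn)
    extL <- setdiff(unique(edges$lnc), lncsIn)
    growT <- any(vapply(extT, function(t) all(vapply(lncsIn, has, logical(1), t = t)),
                        logical(1)))
    growL <- any(vapply(extL, function(l) all(vapply(tfsIn, has, logical(1), l = l)),
                        logical(1)))
    !growT && !growL
}

# All-pairs betweenness by explicit simple-path enumeration (n <= 8),
# normalised by (N-1)(N-2)/2
bruteBetweenness <- function(edges) {
    nodes <- sort(unique(c(edges$tf, edges$lnc)))
    n <- length(nodes)
    adjm <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
    adjm[cbind(edges$tf, edges$lnc)] <- TRUE
    adjm[cbind(edges$lnc, edges$tf)] <- TRUE
    allPaths <- function(s, t) {
        res <- list()
        rec <- function(path) {
            last <- path[length(path)]
            if (last == t) {
                res[[length(res) + 1L]] <<- path
                return(invisible())
            }
            for (nb in nodes[adjm[last, ]])
                if (!(nb %in% path)) rec(c(path, nb))
        }
        rec(s)
        res
    }
    btw <- setNames(numeric(n), nodes)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        ps <- allPaths(nodes[i], nodes[j])
        if (!length(ps)) next
        lens <- lengths(ps)
        sp <- ps[lens == min(lens)]
        inner <- setdiff(nodes, c(nodes[i], nodes[j]))
        for (v in inner)
            btw[v] <- btw[v] +
                mean(vapply(sp, function(p) v %in% p, logical(1)))
    }
    if (n > 2) btw / ((n - 1) * (n - 2) / 2) else btw
}

# Topological coefficient from the set definition
bruteTopoCoef <- function(edges, countAdjacent = TRUE) {
    nodes <- sort(unique(c(edges$tf, edges$lnc)))
    key <- c(paste(edges$tf, edges$lnc), paste(edges$lnc, edges$tf))
    nbrs <- function(v) nodes[paste(v, nodes) %in% key]
    out <- setNames(rep(NA_real_, length(nodes)), nodes)
    for (v in nodes) {
        nv <- nbrs(v)
        if (!length(nv)) next
        partners <- Filter(function(m)
            m != v && length(intersect(nv, nbrs(m))) > 0, nodes)
        if (!length(partners)) next
        J <- vapply(partners, function(m)
            length(intersect(nv, nbrs(m))) +
                as.integer(countAdjacent && m %in% nv), numeric(1))
        out[v] <- mean(J) / length(nv)
    }
    out
}

# Negative log Cox partial likelihood (no ties), minimised numerically;
# independent of survival::coxph
gridSearchCox <- function(x, time, event) {
    nll <- function(b) {
        ord <- order(time)
        x <- x[ord]; time <- time[ord]; event <- event[ord]
        ll <- 0
        for (i in seq_along(time)) {
            if (event[i] == 1) {
                risk <- which(time >= time[i])
                ll <- ll + b * x[i] - log(sum(exp(b * x[risk])))
            }
        }
        -ll
    }
    optimize(nll, c(-20, 20), tol = 1e-9)$minimum
}

# Log-rank chi-square from the textbook observed-minus-expected sums
bruteLogrank <- function(time, event, group) {
    g <- unique(group)
    stopifnot(length(g) == 2)
    ts <- sort(unique(time[event == 1]))
    O1 <- E1 <- V <- 0
    for (t in ts) {
        atRisk <- time >= t
        n <- sum(atRisk)
        n1 <- sum(atRisk & group == g[1])
        d <- sum(time == t & event == 1)
        d1 <- sum(time == t & event == 1 & group == g[1])
        O1 <- O1 + d1
        E1 <- E1 + d * n1 / n
        if (n > 1)
            V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    (O1 - E1)^2 / V
}

# Adjusted Rand index between two labelings
adjustedRand <- function(a, b) {
    tab <- table(a, b)
    comb2 <- function(x) x * (x - 1) / 2
    sumIJ <- sum(comb2(tab))
    sumI <- sum(comb2(rowSums(tab)))
    sumJ <- sum(comb2(colSums(tab)))
    n <- length(a)
    expected <- sumI * sumJ / comb2(n)
    maxIdx <- (sumI + sumJ) / 2
    if (maxIdx == expected) return(1)
    (sumIJ - expected) / (maxIdx - expected)
}

# Stage network object straight from an edge frame (test fixture)
makeNet <- function(edges, stage = "II", alpha = 0.05) {
    e <- data.frame(tf = edges$tf, lnc = edges$lnc,
                    r = if ("r" %in% names(edges)) edges$r else 0.5,
                    p = 0.001, q = 0.01)
    methods::new("StageNetwork", stage = stage, edges = e, alpha = alpha,
                 nTested = nrow(e))
}
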