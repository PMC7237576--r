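test_that("complete and edgeless graphs are handled exactly", {
    k33 <- expand.grid(tf = paste0("t", 1:3), lnc = paste0("l", 1:3),
                       stringsAsFactors = FALSE)
    bs <- enumerateBicliques(k33)
    expect_equal(length(cliques(bs)), 1)
    expect_setequal(cliques(bs)[[1]]$tfs, paste0("t", 1:3))
    expect_setequal(cliques(bs)[[1]]$lncs, paste0("l", 1:3))

    none <- data.frame(tf = character(), lnc = character())
    expect_equal(length(cliques(enumerateBicliques(none))), 0)

    expect_error(enumerateBicliques(data.frame(tf = "a", lnc = "a")),
                 "bipartite")
})

test_that("enumerator equals exhaustive brute force on random graphs", {
    for (seed in 1:30) {
        e <- randomBipartite(6, 6, runif(1, 0.3, 0.7), seed = seed)
        got <- cliqueIdSet(cliques(enumerateBicliques(e)))
        want <- cliqueIdSet(bruteForceBicliques(e))
        expect_identical(got, want)
    }
})

test_that("every enumerated biclique is complete and maximal", {
    for (seed in c(3, 14)) {
        e <- randomBipartite(6, 8, 0.5, seed = seed)
        for (b in cliques(enumerateBicliques(e)))
            expect_true(isMaximalBiclique(e, b$tfs, b$lncs))
    }
})

test_that("enumeration is invariant under node relabelling", {
    e <- randomBipartite(5, 5, 0.5, seed = 8)
    # relabel so that lexicographic iteration order changes
    mapT <- setNames(paste0("z", 5:1), paste0("t", 1:5))
    mapL <- setNames(paste0("y", 5:1), paste0("l", 1:5))
    e2 <- data.frame(tf = unname(mapT[e$tf]), lnc = unname(mapL[e$lnc]))
    a <- cliqueIdSet(cliques(enumerateBicliques(e)))
    b <- cliqueIdSet(cliques(enumerateBicliques(e2)))
    relabel <- function(id) {
        parts <- strsplit(id, "|", fixed = TRUE)[[1]]
        t <- sort(unname(mapT[strsplit(parts[1], "+", fixed = TRUE)[[1]]]))
        l <- sort(unname(mapL[strsplit(parts[2], "+", fixed = TRUE)[[1]]]))
        paste(paste(t, collapse = "+"), paste(l, collapse = "+"), sep = "|")
    }
    expect_setequal(vapply(a, relabel, character(1)), b)
})

test_that("size floor is honoured", {
    e <- randomBipartite(6, 6, 0.6, seed = 5)
    st <- cliqueStats(enumerateBicliques(e, minTfs = 3, minLncs = 2))
    if (nrow(st)) {
        expect_true(all(st$n_tf >= 3))
        expect_true(all(st$n_lnc >= 2))
    }
    # floors equal 1 admit star bicliques
    star <- data.frame(tf = "t1", lnc = c("l1", "l2"))
    expect_equal(length(cliques(enumerateBicliques(star, 1, 1))), 1)
})

test_that("ranking orders by mean specificity with documented tie-breaks", {
    e <- rbind(expand.grid(tf = c("tA", "tB"), lnc = c("l1", "l2", "l3"),
                           stringsAsFactors = FALSE),
               expand.grid(tf = c("tC", "tD"), lnc = c("l4", "l5"),
                           stringsAsFactors = FALSE),
               expand.grid(tf = c("tE", "tF"), lnc = c("l6", "l7"),
                           stringsAsFactors = FALSE))
    bs <- enumerateBicliques(e)
    expect_equal(length(cliques(bs)), 3)
    spec <- c(setNames(rep(1, 6), as.vector(outer(c("tA", "tB"),
                  c("l1", "l2", "l3"), edgeIds))),
              setNames(rep(0.5, 4), as.vector(outer(c("tC", "tD"),
                  c("l4", "l5"), edgeIds))),
              setNames(c(0.5, 0.5, 0.5, 0.5), as.vector(outer(c("tE", "tF"),
                  c("l6", "l7"), edgeIds))))
    rk <- cliqueStats(rankBicliques(bs, spec, topK = 50))
    expect_equal(rk$mean_specificity, c(1, 0.5, 0.5))
    # mean-1 clique first; equal means tie-break lexicographic at equal size
    expect_equal(rk$id[1], "tA+tB|l1+l2+l3")
    expect_true(rk$id[2] < rk$id[3])
    # size beats id when means tie: enlarge one clique's specificity base
    expect_equal(rk$rank, 1:3)
    # topK truncates
    expect_equal(nrow(cliqueStats(rankBicliques(bs, spec, topK = 2))), 2)
    expect_error(rankBicliques(bs, spec[-1], topK = 2), "missing specificity")
})

test_that("mean-specificity ties prefer the larger clique", {
    e <- rbind(expand.grid(tf = c("tA", "tB"), lnc = c("l1", "l2", "l3"),
                           stringsAsFactors = FALSE),
               expand.grid(tf = c("tC", "tD"), lnc = c("l4", "l5"),
                           stringsAsFactors = FALSE))
    bs <- enumerateBicliques(e)
    spec <- setNames(rep(0.7, 10),
                     c(as.vector(outer(c("tA", "tB"), c("l1", "l2", "l3"),
                                       edgeIds)),
                       as.vector(outer(c("tC", "tD"), c("l4", "l5"),
                                       edgeIds))))
    rk <- cliqueStats(rankBicliques(bs, spec))
    expect_equal(rk$size, c(5, 4))
})

test_that("Jaccard coefficient behaves as a set statistic", {
    expect_equal(jaccardIndex(c("a", "b"), c("a", "b")), 1)
    expect_equal(jaccardIndex(c("a"), c("b")), 0)
    expect_equal(jaccardIndex(c("A", "B", "C"), c("B", "C", "D")), 0.5)
    expect_equal(jaccardIndex(c("a", "a", "b"), c("b", "a")), 1)  # duplicates
    expect_error(jaccardIndex(character(0), character(0)), "empty")
    # symmetry on random sets
    set.seed(3)
    for (i in 1:20) {
        x <- sample(letters, 5)
        y <- sample(letters, 7)
        expect_equal(jaccardIndex(x, y), jaccardIndex(y, x))
        expect_gte(jaccardIndex(x, y), 0)
        expect_lte(jaccardIndex(x, y), 1)
    }
})

test_that("clique similarity matrix is symmetric with unit diagonal", {
    e <- randomBipartite(5, 6, 0.6, seed = 21)
    bs <- enumerateBicliques(e)
    if (length(cliques(bs)) >= 2) {
        m <- cliqueSimilarity(bs)
        expect_equal(m, t(m))
        expect_equal(unname(diag(m)), rep(1, nrow(m)))
    }
})

test_that("clique clustering recovers planted block structure", {
    # two perfect blocks
    m <- rbind(cbind(matrix(1, 3, 3), matrix(0, 3, 2)),
               cbind(matrix(0, 2, 3), matrix(1, 2, 2)))
    dimnames(m) <- list(paste0("c", 1:5), paste0("c", 1:5))
    lab <- clusterCliques(m, nClusters = 2)
    expect_equal(adjustedRand(lab, rep(c(1, 2), c(3, 2))), 1)
    expect_error(clusterCliques(m, nClusters = 6), "exceeds")

    # planted 5-block similarity with noise
    set.seed(77)
    truthLab <- rep(1:5, each = 8)
    nse <- matrix(runif(40 * 40, 0, 0.25), 40, 40)
    nse <- (nse + t(nse)) / 2
    sim <- outer(truthLab, truthLab, function(a, b)
        ifelse(a == b, 0.9, 0.05)) + nse
    sim <- pmin(sim, 1)
    diag(sim) <- 1
    dimnames(sim) <- list(paste0("c", 1:40), paste0("c", 1:40))
    lab5 <- clusterCliques(sim, nClusters = 5)
    expect_gte(adjustedRand(lab5, truthLab), 0.9)
})
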