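test_that("candidate graph sampling is complete, deterministic and binomial", {
    # complete bipartite case
    g <- generateCandidateGraph(3, 3, 1.0, seed = 42)
    expect_equal(nrow(g), 9)
    expect_setequal(g$tf, paste0("TF", 1:3))

    # determinism under a fixed seed
    g1 <- generateCandidateGraph(10, 100, 0.05, seed = 1)
    g2 <- generateCandidateGraph(10, 100, 0.05, seed = 1)
    expect_identical(g1, g2)
    expect_false(identical(
        g1, generateCandidateGraph(10, 100, 0.05, seed = 2)))

    # mean edge count across seeds within 3 SDs (of the mean) of the
    # binomial expectation n*p = 2500
    counts <- vapply(1:200, function(s)
        nrow(generateCandidateGraph(50, 500, 0.1, seed = s)), numeric(1))
    se <- sqrt(25000 * 0.1 * 0.9) / sqrt(200)
    expect_lt(abs(mean(counts) - 2500), 3 * se)

    expect_error(generateCandidateGraph(0, 5, 0.5), "positive")
    expect_error(generateCandidateGraph(5, 5, 0), "density")
})

test_that("cohort config rejects out-of-range parameters", {
    expect_error(cohortConfig(nTf = 2, nLnc = 2,
        plantedEdges = data.frame(tf = "TF1", lnc = "LNC1",
                                  stages = "II", r = 1.2)),
        "\\(0, 1\\)")
    expect_error(cohortConfig(nTf = 2, nLnc = 2, censoringRate = 1),
                 "censoringRate")
    expect_error(cohortConfig(nTf = 2, nLnc = 2,
        samplesPerStage = c(II = 10)), "two named stages")
    expect_error(cohortConfig(nTf = 2, nLnc = 2,
        plantedEdges = data.frame(tf = c("TF1", "TF2"), lnc = "LNC1",
                                  stages = "II", r = 0.8)),
        "too strong")
})

test_that("planted edges reach their target correlation, null pairs stay null", {
    pe <- data.frame(tf = "TF1", lnc = "LNC1", stages = "II", r = 0.8)
    cfg <- cohortConfig(nTf = 3, nLnc = 3, candidateDensity = 1,
                        samplesPerStage = c(II = 200, III = 20),
                        plantedEdges = pe, seed = 11)
    co <- simulateCohort(cfg)
    expect_true(all(exprMatrix(co) >= 0))
    sm <- sampleStage(co)
    inII <- names(sm)[sm == "II"]
    ex <- exprMatrix(co)
    # targets are on the latent Gaussian scale; rank correlation is the
    # scale-free check (Spearman of a rho = 0.8 Gaussian pair ~ 0.79)
    rs <- cor(ex["TF1", inII], ex["LNC1", inII], method = "spearman")
    expect_gt(rs, 0.65)
    expect_lt(rs, 0.9)
    # planted edge correlates more strongly in its active stage
    inIII <- names(sm)[sm == "III"]
    expect_gt(rs, cor(ex["TF1", inIII], ex["LNC1", inIII],
                      method = "spearman"))

    # non-planted pairs: |r| < 0.2 in at least 95% of seeds
    nullr <- vapply(1:40, function(s) {
        co <- simulateCohort(cohortConfig(nTf = 3, nLnc = 3,
            candidateDensity = 1, samplesPerStage = c(II = 200, III = 20),
            seed = s))
        sm <- sampleStage(co)
        ii <- names(sm)[sm == "II"]
        cor(exprMatrix(co)["TF2", ii], exprMatrix(co)["LNC2", ii],
            method = "spearman")
    }, numeric(1))
    expect_gte(mean(abs(nullr) < 0.2), 0.95)
})

test_that("null cohorts give nominal pre-FDR type-I error downstream", {
    co <- simulateCohort(cohortConfig(nTf = 10, nLnc = 100,
        candidateDensity = 1, samplesPerStage = c(II = 100, III = 10),
        seed = 5))
    cand <- cohortTruth(co)$candidates
    rawP <- stagenet:::.edgeCorrelations(
        cand, stagenet:::.prepExpr(
            exprMatrix(co)[, sampleStage(co) == "II"]))$p
    frac <- mean(rawP < 0.05)
    expect_gt(frac, 0.02)
    expect_lt(frac, 0.09)
})

test_that("survival simulation honours hazard direction and censoring", {
    set.seed(9)
    expr <- matrix(exp(rnorm(400, 0, 0.5)), nrow = 2,
                   dimnames = list(c("G1", "G2"), paste0("S", 1:200)))
    clique <- list(tfs = "G1", lncs = character(0), beta = c(G1 = 1.5))

    cl0 <- simulateSurvival(expr, clique, censoringRate = 0, seed = 3)
    expect_true(all(cl0$event == 1L))
    expect_true(all(cl0$time > 0))
    # higher expression -> shorter survival
    expect_lt(cor(expr["G1", ], cl0$time, method = "spearman"), -0.3)

    cl3 <- simulateSurvival(expr, clique, censoringRate = 0.3, seed = 3)
    expect_gt(mean(cl3$event == 0), 0.15)
    expect_lt(mean(cl3$event == 0), 0.45)
    expect_true(all(cl3$event %in% c(0L, 1L)))

    expect_error(simulateSurvival(expr, clique, censoringRate = 1), "censoringRate")
    expect_error(simulateSurvival(expr, list(tfs = "NOPE",
        lncs = character(0), beta = c(NOPE = 1))), "missing")

    # null model: median-split log-rank p roughly uniform
    pvals <- vapply(1:200, function(s) {
        cl <- simulateSurvival(expr, NULL, censoringRate = 0.2, seed = s)
        grp <- ifelse(expr["G1", ] > median(expr["G1", ]), "a", "b")
        logrankTest(cl$time, cl$event, grp)$p
    }, numeric(1))
    expect_gt(mean(pvals < 0.05), 0.01)
    expect_lt(mean(pvals < 0.05), 0.12)
    expect_gt(suppressWarnings(ks.test(pvals, "punif")$p.value), 0.01)
})

test_that("cohort generation is byte-deterministic under the seed", {
    cfg <- cohortConfig(nTf = 4, nLnc = 8, candidateDensity = 0.5, seed = 21)
    a <- simulateCohort(cfg)
    b <- simulateCohort(cfg)
    expect_identical(exprMatrix(a), exprMatrix(b))
    expect_identical(clinicalData(a), clinicalData(b))
})
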