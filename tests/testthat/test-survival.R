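test_that("univariate Cox matches a partial-likelihood grid oracle", {
    # 3 subjects, no ties, no censoring: explicit likelihood maximum
    x <- c(0.2, 1.5, 0.7)
    time <- c(5, 2, 9)
    event <- c(1, 1, 1)
    fit <- fitUnivariateCox(x, time, event)
    expect_equal(fit$coef, gridSearchCox(x, time, event), tolerance = 1e-4)
    expect_equal(fit$hr, exp(fit$coef))
    expect_true(fit$lower < fit$hr, fit$hr < fit$upper)

    # a larger no-ties example
    set.seed(10)
    x2 <- rnorm(12)
    tms2 <- rexp(12)
    fit2 <- fitUnivariateCox(x2, tms2, rep(1, 12))
    expect_equal(fit2$coef, gridSearchCox(x2, tms2, rep(1, 12)),
                 tolerance = 1e-4)

    expect_error(fitUnivariateCox(x, time, c(0, 0, 0)), "no events")
    expect_error(fitUnivariateCox(c(1, 1, 1), time, event), "variance")
})

test_that("null predictors give calibrated Cox p-values", {
    set.seed(2)
    ps <- vapply(1:100, function(i) {
        x <- rnorm(80)
        cl <- simulateSurvival(matrix(exp(rnorm(80, 0, 0.5)), 1,
            dimnames = list("G", paste0("S", 1:80))), NULL,
            censoringRate = 0.2, seed = i)
        fitUnivariateCox(x, cl$time, cl$event)$p
    }, numeric(1))
    expect_gt(mean(ps < 0.05), 0.0)
    expect_lt(mean(ps < 0.05), 0.13)
    expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("risk scores are the coefficient-weighted expression sum", {
    m <- methods::new("RiskModel", nodes = c("A", "B"),
        coefficients = c(A = 0.5, B = -0.3), cutoff = 0,
        trainExpr = matrix(1, 2, 3, dimnames = list(c("A", "B"), NULL)),
        table = data.frame(node = c("A", "B")))
    ex <- matrix(c(2, 1), 2, 1, dimnames = list(c("A", "B"), "s1"))
    expect_equal(unname(riskScores(m, ex)), 0.7)
    # linearity: doubling expression doubles the score
    expect_equal(unname(riskScores(m, 2 * ex)), 1.4)
    m0 <- m; m0@coefficients[] <- 0
    expect_equal(unname(riskScores(m0, ex)), 0)
    expect_error(riskScores(m, ex[1, , drop = FALSE]), "missing")
})

test_that("stratification uses the frozen training median, ties to low", {
    set.seed(5)
    n <- 31
    ex <- matrix(exp(rnorm(2 * n, 0, 0.5)), 2,
                 dimnames = list(c("A", "B"), paste0("S", 1:n)))
    cl <- simulateSurvival(ex, list(tfs = "A", lncs = "B",
        beta = c(A = 1, B = 1)), censoringRate = 0.2, seed = 1)
    model <- buildRiskModel(c("A", "B"), ex, cl)
    g <- stratifyRisk(model, ex)
    # odd n: the median sample itself goes to "low"
    expect_equal(sum(g == "high"), (n - 1) / 2)
    expect_equal(sum(g == "low"), (n + 1) / 2)
    # cutoff is frozen: stratifying other data reuses it
    expect_equal(riskCutoff(model),
                 median(riskScores(model, ex)))
    ex2 <- ex * 2
    expect_equal(unname(stratifyRisk(model, ex2)),
                 unname(ifelse(riskScores(model, ex2) > riskCutoff(model),
                               "high", "low")))
    flat <- matrix(1, 2, 4, dimnames = list(c("A", "B"), paste0("T", 1:4)))
    expect_warning(stratifyRisk(model, flat), "degenerate")
})

test_that("high-risk group carries more events under a planted hazard", {
    set.seed(12)
    ex <- matrix(exp(rnorm(300, 0, 0.5)), 2,
                 dimnames = list(c("A", "B"), paste0("S", 1:150)))
    cl <- simulateSurvival(ex, list(tfs = "A", lncs = "B",
        beta = c(A = 1.2, B = 1.2)), censoringRate = 0.2, seed = 4)
    model <- buildRiskModel(c("A", "B"), ex, cl)
    g <- stratifyRisk(model, ex)
    km <- tapply(cl$time, g, median)
    expect_lt(km[["high"]], km[["low"]])
})

test_that("Kaplan-Meier estimate follows the product-limit formula", {
    # two subjects, events at t = 1, 2
    km <- kmCurve(c(1, 2), c(1, 1))
    expect_equal(km$surv, c(0.5, 0))
    # no events: constant 1
    expect_equal(kmCurve(c(3, 4, 5), c(0, 0, 0))$surv, c(1, 1, 1))
    # early censoring leaves S unchanged at the first event
    km2 <- kmCurve(c(0.5, 1, 2), c(0, 1, 1))
    expect_equal(km2$surv[km2$time == 1], 0.5)
    # monotone non-increasing from 1
    set.seed(3)
    km3 <- kmCurve(rexp(50), rbinom(50, 1, 0.7))
    expect_true(all(diff(km3$surv) <= 1e-12))
    expect_true(all(km3$surv >= 0 & km3$surv <= 1))
    # without censoring the KM curve equals the empirical survival function
    tt <- rexp(40)
    km4 <- kmCurve(tt, rep(1, 40))
    expect_equal(km4$surv, 1 - ecdf(tt)(km4$time))
})

test_that("log-rank agrees with textbook arithmetic and is label-symmetric", {
    expect_error(logrankTest(1:4, rep(1, 4), rep("a", 4)), "two groups")
    # duplicated group: no difference
    t0 <- c(1, 3, 5, 1, 3, 5)
    e0 <- c(1, 0, 1, 1, 0, 1)
    g0 <- rep(c("a", "b"), each = 3)
    lr0 <- logrankTest(t0, e0, g0)
    expect_equal(lr0$chisq, 0)
    expect_equal(lr0$p, 1)
    # random small tables vs first-principles O-E computation
    for (seed in 1:10) {
        set.seed(seed)
        tt <- round(rexp(10, 0.1), 1) + 0.1
        ee <- rbinom(10, 1, 0.8)
        gg <- rep(c("a", "b"), each = 5)
        if (sum(ee) == 0) next
        lr <- logrankTest(tt, ee, gg)
        expect_equal(lr$chisq, bruteLogrank(tt, ee, gg), tolerance = 1e-10)
        # symmetric in group labels, invariant to time rescaling
        lr2 <- logrankTest(tt * 12, ee, rev(gg))
        expect_equal(lr$chisq, lr2$chisq, tolerance = 1e-10)
    }
})

test_that("cohort split hits target sizes with balanced clinics", {
    co <- simulateCohort(cohortConfig(nTf = 3, nLnc = 5,
        candidateDensity = 0.5,
        samplesPerStage = c(II = 30, III = 50, IV = 20), seed = 14))
    cl <- clinicalData(co)
    sp <- splitCohort(cl, trainFraction = 0.5, seed = 3)
    expect_equal(length(sp$train), 50)
    expect_equal(length(sp$test), 50)
    expect_true(all(is.na(sp$balance$p) | sp$balance$p > 0.05))
    expect_setequal(c(sp$train, sp$test), seq_len(100))
    # deterministic under the seed
    sp2 <- splitCohort(cl, trainFraction = 0.5, seed = 3)
    expect_identical(sp, sp2)
    expect_error(splitCohort(cl[1:5, ], seed = 1), "at least 10")
})

test_that("multivariate Cox recovers planted covariate effects", {
    set.seed(6)
    n <- 400
    age <- rnorm(n, 60, 10)
    stage <- sample(c("II", "III", "IV"), n, replace = TRUE)
    stageNum <- c(II = 2, III = 3, IV = 4)[stage]
    lp <- 0.05 * (age - 60) + 0.5 * (stageNum - 3)
    time <- rexp(n, rate = 0.02 * exp(lp))
    clin <- data.frame(time = pmax(time, 0.01), event = 1L, age = age,
                       stage = stage, grade = sample(1:3, n, TRUE))
    risk <- sample(c("high", "low"), n, TRUE)
    tab <- multivariateCox(clin, risk)
    expect_setequal(tab$covariate, c("stage", "age", "grade", "risk_group"))
    expect_lt(abs(tab$coef[tab$covariate == "age"] - 0.05), 0.02)
    expect_lt(abs(tab$coef[tab$covariate == "stage"] - 0.5), 0.2)
    # null covariates stay null
    expect_gt(tab$p[tab$covariate == "risk_group"], 0.001)
    expect_equal(tab$hr, exp(tab$coef))
})

test_that("external validation reuses frozen coefficients, tolerates missing nodes", {
    planted <- defaultPlantedStructure()
    cfg <- cohortConfig(nTf = 8, nLnc = 30, candidateDensity = 0.3,
        samplesPerStage = c(II = 40, III = 80, IV = 40),
        plantedEdges = planted$edges, plantedClique = planted$clique,
        seed = 51)
    co <- simulateCohort(cfg)
    cl <- clinicalData(co)
    nodes <- c(planted$clique$tfs, planted$clique$lncs)
    model <- buildRiskModel(nodes, exprMatrix(co), cl)

    # independent cohort from the same generative truth: signal transfers
    cfg2 <- cfg; cfg2$seed <- 151L
    co2 <- simulateCohort(cfg2)
    val <- validateExternal(model, co2)
    expect_false(val$reduced)
    expect_lt(val$logrank$p, 0.05)

    # half the model nodes unavailable: reduced-model path completes
    co3 <- co2[setdiff(rownames(co2), nodes[1:2]), ]
    val3 <- validateExternal(model, co3)
    expect_true(val3$reduced)
    expect_setequal(val3$nodesUsed, nodes[-(1:2)])
    expect_true(is.finite(val3$logrank$chisq))

    co4 <- co2[setdiff(rownames(co2), nodes), ]
    expect_error(validateExternal(model, co4), "no model node")
})
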