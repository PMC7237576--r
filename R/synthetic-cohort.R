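#' @include methods-accessors.R
NULL

#' Configuration for a synthetic staged cohort
#'
#' Describes a synthetic ovarian-cancer-like cohort: bipartite TF/lncRNA
#' gene universe, per-stage sample sizes, a random candidate binding graph,
#' planted stage-specific co-expressed edges, and an optional planted
#' clique whose member expression drives survival.
#'
#' @param nTf,nLnc number of TF and lncRNA genes (positive).
#' @param samplesPerStage named integer vector, stage -> sample count
#'   (default \code{c(II = 20, III = 60, IV = 30)}; at least two stages,
#'   all positive).
#' @param candidateDensity probability in (0, 1] that a TF-lncRNA pair is a
#'   candidate binding edge.
#' @param plantedEdges data.frame with columns \code{tf}, \code{lnc},
#'   \code{stages} (";"-separated stage labels in which the pair is
#'   co-expressed) and \code{r} (target Pearson correlation on the latent
#'   Gaussian scale, in (0, 1)). May be empty.
#' @param plantedClique \code{list(tfs=, lncs=, beta=)}: clique member ids
#'   and a named per-node log-hazard coefficient vector, or NULL.
#' @param censoringRate fraction of subjects censored, in [0, 1).
#' @param seed integer seed controlling every random draw.
#' @return validated list of class \code{cohort_config}.
#' @examples
#' cfg <- cohortConfig(nTf = 4, nLnc = 10, candidateDensity = 0.5)
#' @export
cohortConfig <- function(nTf, nLnc,
                         samplesPerStage = c(II = 20, III = 60, IV = 30),
                         candidateDensity = 0.1,
                         plantedEdges = emptyPlantedEdges(),
                         plantedClique = NULL,
                         censoringRate = 0.3,
                         seed = 1L) {
    if (nTf < 1 || nLnc < 1)
        stop("gene counts must be positive")
    if (length(samplesPerStage) < 2 || is.null(names(samplesPerStage)))
        stop("at least two named stages are required")
    if (any(samplesPerStage < 1))
        stop("all per-stage sample counts must be positive")
    if (candidateDensity <= 0 || candidateDensity > 1)
        stop("candidateDensity must lie in (0, 1]")
    if (censoringRate < 0 || censoringRate >= 1)
        stop("censoringRate must lie in [0, 1)")
    pe <- as.data.frame(plantedEdges)
    if (nrow(pe)) {
        if (!all(c("tf", "lnc", "stages", "r") %in% colnames(pe)))
            stop("plantedEdges needs columns tf, lnc, stages, r")
        if (any(pe$r <= 0 | pe$r >= 1))
            stop("planted correlation targets must lie in (0, 1)")
        bad <- setdiff(unlist(strsplit(pe$stages, ";")), names(samplesPerStage))
        if (length(bad))
            stop("unknown planted stage(s): ", paste(bad, collapse = ", "))
        # a lncRNA may be driven by several TFs in a stage; its latent is
        # then sum_j r_j * z_tfj + noise, which needs sum(r^2) < 1
        key <- unlist(mapply(function(l, s) paste(l, strsplit(s, ";")[[1]]),
                             pe$lnc, pe$stages, SIMPLIFY = FALSE))
        r2 <- tapply(rep(pe$r, lengths(strsplit(pe$stages, ";")))^2,
                     key, sum)
        if (any(r2 >= 1))
            stop("planted correlations too strong: sum of r^2 over the ",
                 "TFs driving one lncRNA in one stage must be < 1")
        dup <- unlist(mapply(function(t, l, s)
            paste(t, l, strsplit(s, ";")[[1]]), pe$tf, pe$lnc, pe$stages,
            SIMPLIFY = FALSE))
        if (anyDuplicated(dup))
            stop("duplicate planted (tf, lnc, stage) entries")
    }
    if (!is.null(plantedClique)) {
        nodes <- c(plantedClique$tfs, plantedClique$lncs)
        if (is.null(plantedClique$beta) ||
            !all(nodes %in% names(plantedClique$beta)))
            stop("plantedClique$beta must name every clique node")
    }
    structure(list(nTf = as.integer(nTf), nLnc = as.integer(nLnc),
                   samplesPerStage = samplesPerStage,
                   candidateDensity = candidateDensity,
                   plantedEdges = pe, plantedClique = plantedClique,
                   censoringRate = censoringRate, seed = as.integer(seed)),
              class = "cohort_config")
}

#' @rdname cohortConfig
#' @export
emptyPlantedEdges <- function()
    data.frame(tf = character(), lnc = character(),
               stages = character(), r = numeric())

#' Sample a random candidate TF-lncRNA binding graph
#'
#' Each of the \code{nTf * nLnc} ordered pairs becomes a candidate edge
#' independently with probability \code{density}; edges receive a binding
#' evidence label (conserved TFBS, ChIP-seq peak, or both) cycling
#' deterministically so both evidence sources are exercised.
#'
#' @param nTf,nLnc positive gene counts; genes are named TF1..TFn, LNC1..LNCn.
#' @param density edge probability in (0, 1].
#' @param seed integer seed.
#' @return data.frame with columns \code{tf}, \code{lnc}, \code{evidence}.
#' @examples
#' g <- generateCandidateGraph(3, 3, 1.0, seed = 7)  # complete bipartite
#' nrow(g)  # 9
#' @export
generateCandidateGraph <- function(nTf, nLnc, density, seed = 1L) {
    if (nTf < 1 || nLnc < 1) stop("gene counts must be positive")
    if (density <= 0 || density > 1) stop("density must lie in (0, 1]")
    tfs <- paste0("TF", seq_len(nTf))
    lncs <- paste0("LNC", seq_len(nLnc))
    all <- expand.grid(tf = tfs, lnc = lncs, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
    set.seed(seed)
    keep <- stats::runif(nrow(all)) < density
    g <- all[keep, , drop = FALSE]
    rownames(g) <- NULL
    ev <- c("conserved_tfbs", "chipseq_peak", "conserved_tfbs;chipseq_peak")
    g$evidence <- ev[(seq_len(nrow(g)) - 1L) %% 3L + 1L]
    g
}

# Gaussian latent scale for the log-normal expression model
.MEANLOG <- 1
.SDLOG <- 1

#' Simulate a staged expression cohort with planted co-expression
#'
#' Draws a latent Gaussian value per gene and sample, independently per
#' stage. For every planted edge active in a stage, the lncRNA's latent
#' value is a correlated copy of its TF's (target correlation \code{r} on
#' the Gaussian scale). Latents are exponentiated to a log-normal,
#' RPKM-like non-negative scale. If the configuration carries a planted
#' clique, survival times are simulated from a proportional-hazards model
#' driven by the clique members' expression (see
#' \code{\link{simulateSurvival}}); otherwise survival is simulated under
#' the null (no expression effect).
#'
#' @param config a \code{\link{cohortConfig}}.
#' @return a \linkS4class{StageCohort}; planted truth is stored in
#'   \code{metadata(x)$truth} (elements \code{candidates}, \code{edges},
#'   \code{clique}).
#' @export
simulateCohort <- function(config) {
    stopifnot(inherits(config, "cohort_config"))
    cand <- generateCandidateGraph(config$nTf, config$nLnc,
                                   config$candidateDensity,
                                   seed = config$seed)
    # planted edges must be candidates: union them in (evidence "both")
    pe <- config$plantedEdges
    if (nrow(pe)) {
        miss <- !(edgeIds(pe$tf, pe$lnc) %in% edgeIds(cand$tf, cand$lnc))
        if (any(miss))
            cand <- rbind(cand, data.frame(
                tf = pe$tf[miss], lnc = pe$lnc[miss],
                evidence = "conserved_tfbs;chipseq_peak"))
    }
    cand <- cand[order(cand$tf, cand$lnc), , drop = FALSE]
    rownames(cand) <- NULL

    genes <- c(paste0("TF", seq_len(config$nTf)),
               paste0("LNC", seq_len(config$nLnc)))
    if (!is.null(config$plantedClique))
        stopifnot(all(c(config$plantedClique$tfs,
                        config$plantedClique$lncs) %in% genes))
    stages <- names(config$samplesPerStage)
    set.seed(config$seed + 1L)
    blocks <- vector("list", length(stages))
    stageOf <- character(0)
    for (si in seq_along(stages)) {
        s <- stages[si]
        n <- config$samplesPerStage[[s]]
        z <- matrix(stats::rnorm(length(genes) * n), nrow = length(genes),
                    dimnames = list(genes, NULL))
        if (nrow(pe)) {
            act <- pe[vapply(strsplit(pe$stages, ";"),
                             function(a) s %in% a, logical(1)), , drop = FALSE]
            for (l in unique(act$lnc)) {
                rows <- act[act$lnc == l, , drop = FALSE]
                drive <- crossprod(rows$r, z[rows$tf, , drop = FALSE])
                z[l, ] <- as.numeric(drive) +
                    sqrt(1 - sum(rows$r^2)) * z[l, ]
            }
        }
        blocks[[si]] <- z
        stageOf <- c(stageOf, rep(s, n))
    }
    z <- do.call(cbind, blocks)
    colnames(z) <- sprintf("S%03d", seq_len(ncol(z)))
    names(stageOf) <- colnames(z)
    expr <- exp(.MEANLOG + .SDLOG * z)

    clin <- simulateSurvival(expr, config$plantedClique,
                             censoringRate = config$censoringRate,
                             seed = config$seed + 2L)
    clin$stage <- stageOf
    truth <- list(candidates = cand, edges = pe,
                  clique = config$plantedClique)
    se <- SummarizedExperiment(assays = list(expr = expr),
                               colData = DataFrame(clin,
                                                   row.names = colnames(expr)))
    out <- methods::new("StageCohort", se)
    metadata(out)$truth <- truth
    out
}

#' Simulate survival under a proportional-hazards model
#'
#' Event times are exponential with hazard
#' \code{lambda0 * exp(lp)} where \code{lp = sum_i beta_i * Exp(i)} over
#' planted clique members (centred across samples so that \code{lambda0}
#' sets the time scale in months). Censoring is independent: each subject
#' is censored with probability \code{censoringRate}, and a censored
#' subject's observed time is uniform on (0, its event time). Age and
#' histological grade covariates are drawn independently of survival.
#'
#' @param expr genes-by-samples non-negative expression matrix.
#' @param plantedClique \code{list(tfs=, lncs=, beta=)} or NULL for the
#'   null model (no expression effect).
#' @param censoringRate fraction in [0, 1).
#' @param seed integer seed.
#' @param lambda0 baseline hazard per month (default 0.02, giving a median
#'   event time around 35 months at the centred linear predictor).
#' @return data.frame: \code{time} (months, > 0), \code{event} (0/1),
#'   \code{age}, \code{grade}.
#' @export
simulateSurvival <- function(expr, plantedClique = NULL, censoringRate = 0.3,
                             seed = 1L, lambda0 = 0.02) {
    if (censoringRate < 0 || censoringRate >= 1)
        stop("censoringRate must lie in [0, 1)")
    n <- ncol(expr)
    lp <- rep(0, n)
    if (!is.null(plantedClique)) {
        nodes <- c(plantedClique$tfs, plantedClique$lncs)
        if (!all(nodes %in% rownames(expr)))
            stop("clique nodes missing from expression matrix")
        b <- plantedClique$beta[nodes]
        lp <- as.numeric(crossprod(expr[nodes, , drop = FALSE], b))
        lp <- lp - mean(lp)
    }
    set.seed(seed)
    t_event <- stats::rexp(n, rate = lambda0 * exp(lp))
    t_event <- pmax(t_event, 0.01)
    cens <- stats::runif(n) < censoringRate
    time <- ifelse(cens, stats::runif(n, 0, t_event), t_event)
    time <- pmax(time, 0.01)
    age <- pmin(pmax(round(stats::rnorm(n, 60, 10)), 30), 90)
    grade <- sample(1:3, n, replace = TRUE, prob = c(0.1, 0.45, 0.45))
    data.frame(time = time, event = as.integer(!cens), age = age,
               grade = grade, row.names = colnames(expr))
}

#' Write toy annotation files consistent with a candidate graph
#'
#' Emits a GTF of one transcript per lncRNA (alternating strand, loci
#' spaced 100 kb so promoter windows never collide) and two BED files of
#' binding intervals (conserved TFBS and ChIP-seq peaks) placed at the
#' centre of each target lncRNA's promoter window, so that
#' \code{\link{findCandidates}} on the emitted files recovers exactly the
#' candidate graph.
#'
#' @param candidates data.frame (\code{tf}, \code{lnc}, \code{evidence}).
#' @param dir output directory (created if needed).
#' @param up,down promoter window extents in bp used for placement.
#' @return invisibly, named paths (\code{gtf}, \code{tfbs}, \code{peaks}).
#' @export
writeAnnotationFiles <- function(candidates, dir, up = 5000, down = 1000) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    lncs <- sort(unique(candidates$lnc))
    k <- seq_along(lncs)
    strand <- ifelse(k %% 2L == 1L, "+", "-")
    tss <- 50000L + (k - 1L) * 100000L           # 1-based TSS positions
    width <- 1000L
    start <- ifelse(strand == "+", tss, tss - width + 1L)
    end <- ifelse(strand == "+", tss + width - 1L, tss)
    tx <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(start, end), strand = strand,
        type = "transcript", source = "stagenet",
        gene_id = lncs, transcript_id = paste0(lncs, ".1"),
        gene_name = lncs)
    gtf <- file.path(dir, "annotation.gtf")
    rtracklayer::export(tx, gtf, format = "gtf")

    # one 50-bp site per edge, centred in the promoter window
    win <- suppressWarnings(GenomicRanges::promoters(tx, upstream = up,
                                                     downstream = down))
    win <- GenomicRanges::trim(win)
    site1 <- GenomicRanges::resize(win, width = 50, fix = "center")
    idx <- match(candidates$lnc, lncs)
    mk <- function(rows) {
        gr <- GenomicRanges::GRanges("chr1",
            IRanges::IRanges(GenomicRanges::start(site1)[idx[rows]],
                             GenomicRanges::end(site1)[idx[rows]]),
            strand = "*")
        S4Vectors::mcols(gr)$name <- candidates$tf[rows]
        S4Vectors::mcols(gr)$score <- 800
        sort(gr)
    }
    has <- function(tag) grepl(tag, candidates$evidence, fixed = TRUE)
    tfbs <- file.path(dir, "tfbs.bed")
    peaks <- file.path(dir, "peaks.bed")
    rtracklayer::export(mk(which(has("conserved_tfbs"))), tfbs, format = "bed")
    rtracklayer::export(mk(which(has("chipseq_peak"))), peaks, format = "bed")
    invisible(c(gtf = gtf, tfbs = tfbs, peaks = peaks))
}

#' Write cohort tables to disk
#'
#' Expression TSV (genes x samples), clinical TSV and planted-truth JSON.
#'
#' @param cohort a \linkS4class{StageCohort}.
#' @param dir output directory.
#' @return invisibly, named file paths.
#' @export
writeCohort <- function(cohort, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    ep <- file.path(dir, "expression.tsv")
    cp <- file.path(dir, "clinical.tsv")
    tp <- file.path(dir, "truth.json")
    ex <- exprMatrix(cohort)
    utils::write.table(data.frame(gene = rownames(ex), ex,
                                  check.names = FALSE),
                       ep, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(clinicalData(cohort), cp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(cohortTruth(cohort), tp, auto_unbox = TRUE,
                         digits = NA, null = "null")
    invisible(c(expression = ep, clinical = cp, truth = tp))
}
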