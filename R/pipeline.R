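#' @include methods-accessors.R
NULL

#' Default planted structure for the synthetic pipeline config
#'
#' A five-node clique (2 TFs x 3 lncRNAs) co-expressed in stage III whose
#' members carry a positive log-hazard effect, plus single-stage edge
#' groups in each stage and one ubiquitous (all-stage) group, so that
#' activity clustering, specificity ranking and survival modelling all
#' have signal to find.
#'
#' @return list with \code{edges} (data.frame) and \code{clique}.
#' @export
defaultPlantedStructure <- function() {
    cliqueTfs <- c("TF1", "TF2")
    cliqueLncs <- c("LNC1", "LNC2", "LNC3")
    cliqueEdges <- expand.grid(tf = cliqueTfs, lnc = cliqueLncs,
                               KEEP.OUT.ATTRS = FALSE,
                               stringsAsFactors = FALSE)
    cliqueEdges$stages <- "III"
    cliqueEdges$r <- 0.7
    single <- rbind(
        data.frame(tf = "TF3", lnc = paste0("LNC", 11:14),
                   stages = "II", r = 0.8),
        data.frame(tf = "TF4", lnc = paste0("LNC", 15:18),
                   stages = "III", r = 0.7),
        data.frame(tf = "TF5", lnc = paste0("LNC", 19:22),
                   stages = "IV", r = 0.75))
    ubiq <- data.frame(tf = "TF6", lnc = paste0("LNC", 23:26),
                       stages = "II;III;IV", r = 0.6)
    nodes <- c(cliqueTfs, cliqueLncs)
    list(edges = rbind(cliqueEdges, single, ubiq),
         clique = list(tfs = cliqueTfs, lncs = cliqueLncs,
                       beta = stats::setNames(rep(0.1, length(nodes)),
                                              nodes)))
}

#' Pipeline configuration
#'
#' Validated bundle of every knob of the end-to-end analysis, with the
#' study's standard thresholds as defaults: promoter window 5 kb up / 1 kb
#' down, FDR alpha 0.05, clique size floor 2 TFs x 2 lncRNAs, top 50
#' cliques, 7 activity groups, 5 clique clusters, housekeeping specificity
#' threshold 0.15, 50/50 training split.
#'
#' @param cohort a \code{\link{cohortConfig}} describing the synthetic
#'   cohort (default: 12 TFs x 60 lncRNAs at density 0.25 with the
#'   \code{\link{defaultPlantedStructure}}).
#' @param alpha per-stage FDR threshold.
#' @param up,down promoter window in bp.
#' @param minTfs,minLncs biclique size floor.
#' @param topK top cliques retained after specificity ranking.
#' @param kmeansK activity groups for K-means.
#' @param nClusters clique clusters.
#' @param housekeepingThreshold specificity cutoff for the housekeeping
#'   fraction.
#' @param trainFraction training share of the survival split.
#' @param seed master seed; per-stage seeds are derived by fixed small
#'   offsets (cohort: seed; K-means: seed + 10; split: seed + 20) so any
#'   stage can be rerun in isolation.
#' @return list of class \code{pipeline_config}.
#' @export
pipelineConfig <- function(cohort = NULL, alpha = 0.05, up = 5000,
                           down = 1000, minTfs = 2, minLncs = 2,
                           topK = 50, kmeansK = 7, nClusters = 5,
                           housekeepingThreshold = 0.15,
                           trainFraction = 0.5, seed = 1L) {
    if (is.null(cohort)) {
        planted <- defaultPlantedStructure()
        cohort <- cohortConfig(nTf = 12, nLnc = 60,
                               candidateDensity = 0.25,
                               plantedEdges = planted$edges,
                               plantedClique = planted$clique,
                               censoringRate = 0.3, seed = seed)
    }
    stopifnot(inherits(cohort, "cohort_config"),
              alpha >= 0, alpha <= 1, up >= 0, down >= 0,
              minTfs >= 1, minLncs >= 1, topK >= 1, kmeansK >= 2,
              nClusters >= 1, trainFraction > 0, trainFraction < 1)
    structure(list(cohort = cohort, alpha = alpha, up = up, down = down,
                   minTfs = minTfs, minLncs = minLncs, topK = topK,
                   kmeansK = kmeansK, nClusters = nClusters,
                   housekeepingThreshold = housekeepingThreshold,
                   trainFraction = trainFraction, seed = as.integer(seed)),
              class = "pipeline_config")
}

#' Run the full stage-network analysis end-to-end
#'
#' Synthesize the cohort, write and re-read toy annotation/binding files
#' (an internal round-trip consistency check on the candidate graph),
#' build the per-stage networks and their topology tables, compute
#' activity profiles, specificity scores and K-means activity groups,
#' enumerate and rank maximal bicliques on the union network, cluster the
#' top cliques by Jaccard similarity, and evaluate the top clique's
#' prognostic power (balanced training/testing split, risk model,
#' Kaplan-Meier curves, log-rank tests, multivariate adjustment). All
#' tables are written under \code{outdir} together with a run manifest;
#' reruns with the same config are identical except the manifest
#' timestamp.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param outdir output directory.
#' @return invisibly, a list with the cohort, networks, profiles, clique
#'   sets, risk model, survival statistics and the manifest.
#' @export
runPipeline <- function(config, outdir) {
    stopifnot(inherits(config, "pipeline_config"))
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    step <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
    }

    cohort <- step("synth", simulateCohort(config$cohort))
    truth <- cohortTruth(cohort)
    files <- step("annotation", writeAnnotationFiles(
        truth$candidates, file.path(outdir, "inputs"),
        up = config$up, down = config$down))
    candidates <- step("candidates", findCandidates(
        files["gtf"], files["tfbs"], files["peaks"],
        up = config$up, down = config$down))
    want <- truth$candidates[order(truth$candidates$tf,
                                   truth$candidates$lnc), ]
    if (!identical(candidates[, c("tf", "lnc", "evidence")],
                   want[, c("tf", "lnc", "evidence")]))
        stop("pipeline stage 'candidates' failed: annotation round-trip ",
             "did not recover the candidate graph")
    utils::write.table(candidates, file.path(outdir, "candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    networks <- step("networks", buildStageNetworks(candidates, cohort,
                                                    alpha = config$alpha))
    for (s in names(networks)) {
        utils::write.table(networkEdges(networks[[s]]),
                           file.path(outdir, paste0("edges_", s, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        if (nrow(networkEdges(networks[[s]]))) {
            deg <- nodeDegree(networks[[s]])
            tc <- topologicalCoefficient(networks[[s]])
            btw <- betweennessCentrality(networks[[s]])
            utils::write.table(
                data.frame(node = names(deg), degree = as.integer(deg),
                           topological_coefficient = tc[names(deg)],
                           betweenness = btw[names(deg)]),
                file.path(outdir, paste0("nodes_", s, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
        }
    }
    venn <- step("overlap", networkOverlap(networks))
    jsonlite::write_json(venn, file.path(outdir, "venn.json"),
                         auto_unbox = FALSE, digits = NA)

    # degenerate threshold (e.g. alpha = 0): no edges anywhere; write empty
    # downstream tables and stop early with a complete manifest
    if (!sum(vapply(networks, function(n) nrow(networkEdges(n)),
                    numeric(1)))) {
        for (f in c("activity.tsv", "cliques.tsv", "risk.tsv"))
            writeLines(character(0), file.path(outdir, f))
        manifest <- list(
            package = "stagenet",
            version = as.character(utils::packageVersion("stagenet")),
            seed = config$seed,
            thresholds = config[c("alpha", "up", "down", "minTfs",
                                  "minLncs", "topK", "kmeansK", "nClusters",
                                  "housekeepingThreshold", "trainFraction")],
            counts = list(candidates = nrow(candidates),
                          edges_per_stage = lapply(networks, function(n)
                              nrow(networkEdges(n))),
                          profiles = 0L, cliques = 0L, top_cliques = 0L),
            timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
        jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
        return(invisible(list(cohort = cohort, candidates = candidates,
                              networks = networks, overlap = venn,
                              manifest = manifest)))
    }

    profiles <- step("dynamics", activityProfiles(networks, cohort))
    kEff <- min(config$kmeansK, length(profiles@tf))
    if (kEff < config$kmeansK)
        warning("fewer profiles than kmeansK; using k = ", kEff)
    if (kEff >= 2)
        profiles <- step("dynamics", clusterActivity(
            profiles, k = kEff, seed = config$seed + 10L))
    spec <- specificity(profiles)
    rawM <- rawCorrelations(profiles)
    actM <- activityMatrix(profiles)
    rownames(rawM) <- rownames(actM) <- NULL
    actTab <- data.frame(edge = names(spec), rawM, actM,
                         specificity = unname(spec),
                         group = unname(activityGroups(profiles)),
                         check.names = FALSE)
    colnames(actTab) <- c("edge", paste0("r_", colnames(rawM)),
                          paste0("act_", colnames(actM)),
                          "specificity", "group")
    utils::write.table(actTab, file.path(outdir, "activity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    union <- unionNetwork(networks)
    bcl <- step("cliques", enumerateBicliques(union,
                                              minTfs = config$minTfs,
                                              minLncs = config$minLncs))
    top <- step("cliques", rankBicliques(bcl, spec, topK = config$topK))
    if (!length(cliques(top)))
        stop("pipeline stage 'cliques' failed: no biclique meets the ",
             "size floor; lower minTfs/minLncs or alpha")
    nClEff <- min(config$nClusters, length(cliques(top)))
    sim <- cliqueSimilarity(top)
    cls <- step("cliques", clusterCliques(sim, nClusters = nClEff))
    topStats <- cliqueStats(top)
    topStats$cluster <- as.integer(cls[topStats$id])
    utils::write.table(topStats, file.path(outdir, "cliques.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(id = rownames(sim), sim,
                                  check.names = FALSE),
                       file.path(outdir, "clique_similarity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    clin <- clinicalData(cohort)
    expr <- exprMatrix(cohort)
    split <- step("survival", splitCohort(clin,
                                          trainFraction = config$trainFraction,
                                          seed = config$seed + 20L))
    nodes <- c(cliques(top)[[1]]$tfs, cliques(top)[[1]]$lncs)
    model <- step("survival", buildRiskModel(
        nodes, expr[, split$train, drop = FALSE],
        clin[split$train, , drop = FALSE]))
    surv <- list()
    riskTab <- NULL
    for (part in c("train", "test")) {
        idx <- split[[part]]
        scores <- riskScores(model, expr[, idx, drop = FALSE])
        groups <- stratifyRisk(model, expr[, idx, drop = FALSE])
        lr <- if (length(unique(groups)) == 2)
            logrankTest(clin$time[idx], clin$event[idx], groups)
        else list(chisq = NA_real_, p = NA_real_)
        km <- do.call(rbind, lapply(split(seq_along(idx), groups),
            function(j) {
                g <- unname(groups[j[1]])
                cbind(part = part, group = g,
                      kmCurve(clin$time[idx][j], clin$event[idx][j]))
            }))
        utils::write.table(km,
            file.path(outdir, paste0("km_", part, ".tsv")),
            sep = "\t", quote = FALSE, row.names = FALSE)
        riskTab <- rbind(riskTab,
            data.frame(sample = clin$sample[idx], part = part,
                       score = unname(scores), group = unname(groups)))
        surv[[part]] <- lr
    }
    utils::write.table(riskTab, file.path(outdir, "risk.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    grpAll <- stratifyRisk(model, expr)
    mvTab <- step("survival", multivariateCox(clin, grpAll))
    utils::write.table(mvTab, file.path(outdir, "multivariate.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    manifest <- list(
        package = "stagenet",
        version = as.character(utils::packageVersion("stagenet")),
        seed = config$seed,
        thresholds = config[c("alpha", "up", "down", "minTfs", "minLncs",
                              "topK", "kmeansK", "nClusters",
                              "housekeepingThreshold", "trainFraction")],
        counts = list(
            candidates = nrow(candidates),
            edges_per_stage = lapply(networks, function(n)
                nrow(networkEdges(n))),
            profiles = length(profiles@tf),
            cliques = length(cliques(bcl)),
            top_cliques = length(cliques(top))),
        dynamics = list(
            mean_specificity = mean(spec, na.rm = TRUE),
            housekeeping_fraction = housekeepingFraction(
                spec, config$housekeepingThreshold)),
        survival = list(
            clique = paste(nodes, collapse = "+"),
            balance_attempts = split$attempts,
            logrank_train_p = surv$train$p,
            logrank_test_p = surv$test$p,
            risk_group_hr = mvTab$hr[mvTab$covariate == "risk_group"]),
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    invisible(list(cohort = cohort, candidates = candidates,
                   networks = networks, overlap = venn,
                   profiles = profiles, bicliques = bcl,
                   topCliques = top, cliqueClusters = cls, split = split,
                   model = model, survivalTests = surv,
                   multivariate = mvTab, manifest = manifest))
}

#' Read a run manifest, dropping volatile fields
#'
#' Convenience for determinism checks: parses \code{manifest.json} and
#' removes the timestamp.
#'
#' @param outdir pipeline output directory.
#' @return list.
#' @export
readManifest <- function(outdir) {
    m <- jsonlite::read_json(file.path(outdir, "manifest.json"))
    m$timestamp <- NULL
    m
}
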