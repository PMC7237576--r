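#' @include methods-accessors.R
NULL

#' Normalise per-stage edge activity scores
#'
#' Within each stage (column), the raw co-expression coefficients of all
#' edges are z-scored — \code{z = (x - mu) / sigma} with the sample (n - 1)
#' standard deviation — and then shifted by subtracting the stage minimum,
#' so every stage's activity scores are non-negative with minimum exactly
#' 0 and comparable distributions across stages.
#'
#' @param raw edges-by-stages numeric matrix of co-expression coefficients.
#' @return matrix of the same shape; each column has minimum 0.
#' @export
normalizeActivity <- function(raw) {
    raw <- as.matrix(raw)
    if (nrow(raw) < 2)
        stop("need at least two edges per stage to define sigma")
    mu <- colMeans(raw)
    sdev <- apply(raw, 2, stats::sd)
    if (any(sdev == 0))
        stop("zero activity dispersion in stage(s): ",
             paste(colnames(raw)[sdev == 0], collapse = ", "))
    z <- sweep(sweep(raw, 2, mu), 2, sdev, "/")
    sweep(z, 2, apply(z, 2, min))
}

#' Stage-specificity score of an activity profile
#'
#' For a profile of N per-stage components, each component is normalised to
#' the profile maximum and the score is \code{sum_i (1 - x_i / max(x)) /
#' (N - 1)}. A profile equal across all stages scores 0 (ubiquitous,
#' housekeeping-like activity); a profile active in exactly one stage
#' scores 1. Negative components (negative correlations) are clamped to 0
#' first, which keeps the score inside [0, 1]. An all-zero profile has no
#' defined maximum and returns \code{NA} with a warning.
#'
#' @param x numeric vector of N >= 2 per-stage components.
#' @return score in [0, 1], or NA for an all-zero profile.
#' @examples
#' specificityScore(c(1, 0, 0))        # 1
#' specificityScore(c(0.5, 0.5, 0.5))  # 0
#' specificityScore(c(0.8, 0.4, 0.2))  # 0.625
#' @export
specificityScore <- function(x) {
    if (length(x) < 2) stop("need at least two stages")
    x <- pmax(x, 0)
    m <- max(x)
    if (m == 0) {
        warning("all-zero profile: specificity undefined")
        return(NA_real_)
    }
    sum(1 - x / m) / (length(x) - 1)
}

#' @rdname specificityScore
#' @param mat edges-by-stages matrix; scores are computed row-wise (without
#'   the per-row warning; all-zero rows return NA).
#' @export
specificityScores <- function(mat) {
    mat <- pmax(as.matrix(mat), 0)
    if (ncol(mat) < 2) stop("need at least two stages")
    m <- apply(mat, 1, max)
    out <- rep(NA_real_, nrow(mat))
    ok <- m > 0
    out[ok] <- rowSums(1 - mat[ok, , drop = FALSE] / m[ok]) /
        (ncol(mat) - 1)
    out
}

#' Cross-stage activity profiles for network edges
#'
#' The profile universe is every edge significant in at least one stage
#' network. For each such edge the Pearson coefficient is computed in every
#' stage (whether or not the edge passed that stage's filter), giving the
#' raw profile; raw profiles are z-normalised per stage
#' (\code{\link{normalizeActivity}}) and scored for stage specificity
#' (negatives clamped, \code{\link{specificityScores}}).
#'
#' @param networks named list of \linkS4class{StageNetwork}s.
#' @param cohort the \linkS4class{StageCohort} the networks came from.
#' @param transform expression transform before correlation; must match
#'   the one used for the networks (default \code{"log2"}).
#' @return an \linkS4class{ActivityProfiles} (groups unset).
#' @export
activityProfiles <- function(networks, cohort,
                             transform = c("log2", "none")) {
    stages <- names(networks)
    univ <- unique(do.call(rbind, lapply(networks, function(n)
        networkEdges(n)[, c("tf", "lnc")])))
    univ <- univ[order(univ$tf, univ$lnc), , drop = FALSE]
    if (!nrow(univ)) stop("no significant edges in any stage")
    expr <- .prepExpr(exprMatrix(cohort), transform)
    sm <- sampleStage(cohort)
    raw <- vapply(stages, function(s) {
        .edgeCorrelations(univ, expr[, names(sm)[sm == s],
                                     drop = FALSE])$r
    }, numeric(nrow(univ)))
    raw <- matrix(raw, nrow = nrow(univ),
                  dimnames = list(NULL, stages))
    act <- normalizeActivity(raw)
    spec <- specificityScores(raw)
    methods::new("ActivityProfiles", tf = univ$tf, lnc = univ$lnc,
                 raw = raw, activity = act, specificity = spec,
                 group = rep(NA_integer_, nrow(univ)))
}

#' K-means clustering of activity profiles
#'
#' Clusters the normalised activity profiles into k groups of cross-stage
#' regulatory behaviour (stage-restricted vs ubiquitous edges). Labels are
#' relabelled canonically by descending cluster size so results are
#' reproducible across platforms, and the fit is deterministic under the
#' seed (k-means with many random restarts).
#'
#' @param profiles an \linkS4class{ActivityProfiles}.
#' @param k number of groups (default 7); must satisfy
#'   \code{2 <= k <= nrow}.
#' @param seed integer seed.
#' @param nstart random restarts (default 50).
#' @return the profiles object with \code{activityGroups} filled in.
#' @export
clusterActivity <- function(profiles, k = 7, seed = 1L, nstart = 50) {
    m <- activityMatrix(profiles)
    if (k < 2 || k > nrow(m))
        stop("k must lie in [2, number of profiles]")
    ndistinct <- nrow(unique(m))
    if (ndistinct < k)
        warning("only ", ndistinct, " distinct profiles for k = ", k,
                ": clusters will be degenerate")
    set.seed(seed)
    km <- suppressWarnings(
        stats::kmeans(m, centers = min(k, ndistinct), nstart = nstart,
                      iter.max = 100))
    cl <- km$cluster
    sizes <- sort(table(cl), decreasing = TRUE)
    relabel <- stats::setNames(seq_along(sizes), names(sizes))
    profiles@group <- as.integer(relabel[as.character(cl)])
    methods::validObject(profiles)
    profiles
}

#' Fraction of edges above the housekeeping specificity threshold
#'
#' Fraction of specificity scores strictly greater than \code{threshold}
#' (default 0.15, the conventional cutoff below which an expression profile
#' is considered housekeeping-like, i.e. not stage-specific).
#'
#' @param specificities numeric vector (NAs ignored).
#' @param threshold housekeeping cutoff.
#' @return fraction in [0, 1].
#' @export
housekeepingFraction <- function(specificities, threshold = 0.15) {
    s <- specificities[!is.na(specificities)]
    if (!length(s)) stop("no defined specificity scores")
    mean(s > threshold)
}
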