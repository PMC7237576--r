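#' @include methods-accessors.R
#' @importFrom survival Surv coxph survfit survdiff
NULL

#' Univariate Cox proportional-hazards fit for one gene
#'
#' Association between survival and a single expression vector, fitted by
#' partial likelihood with Efron tie handling. Returns the log hazard
#' ratio, HR with 95% Wald confidence interval and Wald p-value. Fits that
#' fail or do not converge are flagged rather than raised so callers can
#' exclude the node with a warning.
#'
#' @param x per-sample expression values.
#' @param time,event survival in months (> 0) and 0/1 event indicator.
#' @return list: \code{coef}, \code{hr}, \code{lower}, \code{upper},
#'   \code{p}, \code{converged}.
#' @export
fitUnivariateCox <- function(x, time, event) {
    if (sum(event) < 1) stop("no events observed")
    if (stats::sd(x) == 0) stop("zero predictor variance")
    fit <- tryCatch(
        coxph(Surv(time, event) ~ x, ties = "efron"),
        error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit) || is.na(stats::coef(fit)))
        return(list(coef = NA_real_, hr = NA_real_, lower = NA_real_,
                    upper = NA_real_, p = NA_real_, converged = FALSE))
    b <- unname(stats::coef(fit))
    se <- sqrt(unname(stats::vcov(fit)[1, 1]))
    list(coef = b, hr = exp(b), lower = exp(b - 1.96 * se),
         upper = exp(b + 1.96 * se),
         p = 2 * stats::pnorm(-abs(b / se)), converged = TRUE)
}

#' Fit a clique risk model on a training cohort
#'
#' Each clique node gets a univariate Cox coefficient on the training
#' samples; the risk score of a sample is the coefficient-weighted sum of
#' the node expressions, and the training median risk score is frozen as
#' the stratification cutoff. Nodes whose fit does not converge are
#' excluded with a warning.
#'
#' @param nodes clique member gene ids.
#' @param expr genes-by-samples training expression.
#' @param clinical data.frame with \code{time} and \code{event} aligned to
#'   the columns of \code{expr}.
#' @return a \linkS4class{RiskModel}.
#' @export
buildRiskModel <- function(nodes, expr, clinical) {
    stopifnot(all(nodes %in% rownames(expr)),
              nrow(clinical) == ncol(expr))
    fits <- lapply(nodes, function(g)
        fitUnivariateCox(expr[g, ], clinical$time, clinical$event))
    ok <- vapply(fits, `[[`, logical(1), "converged")
    if (!all(ok))
        warning("excluding non-converged node(s): ",
                paste(nodes[!ok], collapse = ", "))
    if (!any(ok)) stop("no clique node produced a stable Cox fit")
    nodes <- nodes[ok]
    fits <- fits[ok]
    co <- stats::setNames(vapply(fits, `[[`, numeric(1), "coef"), nodes)
    tab <- data.frame(
        node = nodes, coef = co,
        hr = vapply(fits, `[[`, numeric(1), "hr"),
        lower = vapply(fits, `[[`, numeric(1), "lower"),
        upper = vapply(fits, `[[`, numeric(1), "upper"),
        p = vapply(fits, `[[`, numeric(1), "p"), row.names = NULL)
    tr <- expr[nodes, , drop = FALSE]
    model <- methods::new("RiskModel", nodes = nodes, coefficients = co,
                          cutoff = 0, trainExpr = tr, table = tab)
    model@cutoff <- stats::median(riskScores(model, tr))
    model
}

#' Risk scores under a fitted model
#'
#' Linear combination \code{sum_i r_i * Exp(i)} of node expression weighted
#' by the model's univariate Cox coefficients.
#'
#' @param model a \linkS4class{RiskModel}.
#' @param expr genes-by-samples matrix containing all model nodes.
#' @return named numeric vector of per-sample scores.
#' @export
riskScores <- function(model, expr) {
    miss <- setdiff(model@nodes, rownames(expr))
    if (length(miss))
        stop("model nodes missing from expression: ",
             paste(miss, collapse = ", "))
    as.numeric(crossprod(expr[model@nodes, , drop = FALSE],
                         model@coefficients)) |>
        stats::setNames(colnames(expr))
}

#' Stratify samples by the frozen training cutoff
#'
#' Scores strictly above the cutoff are "high" risk; scores at or below
#' (ties included) are "low". The cutoff always comes from the fitted
#' model, never from the cohort being stratified.
#'
#' @param model a \linkS4class{RiskModel}.
#' @param expr genes-by-samples matrix.
#' @return named character vector "high"/"low".
#' @export
stratifyRisk <- function(model, expr) {
    s <- riskScores(model, expr)
    g <- ifelse(s > model@cutoff, "high", "low")
    if (length(unique(g)) == 1)
        warning("degenerate stratification: all samples in one group")
    g
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate: right-continuous, starts at 1, non-increasing.
#'
#' @param time,event survival times and 0/1 event indicators.
#' @return data.frame (\code{time}, \code{n_risk}, \code{n_event},
#'   \code{surv}).
#' @export
kmCurve <- function(time, event) {
    fit <- survfit(Surv(time, event) ~ 1)
    data.frame(time = fit$time, n_risk = fit$n.risk,
               n_event = fit$n.event, surv = fit$surv)
}

#' Two-group log-rank test
#'
#' 1-df chi-square from observed-minus-expected events over the pooled
#' risk sets.
#'
#' @param time,event survival data for all samples.
#' @param group two-level group labels.
#' @return list: \code{chisq}, \code{p}.
#' @export
logrankTest <- function(time, event, group) {
    if (length(unique(group)) != 2) stop("need exactly two groups")
    if (sum(event) < 1) stop("no events observed")
    sd <- survdiff(Surv(time, event) ~ group)
    list(chisq = unname(sd$chisq),
         p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Random training/testing split with clinical balance checks
#'
#' Randomly partitions samples into training (\code{round(n * fraction)})
#' and testing sets and verifies that the two halves are clinically
#' comparable: chi-square tests for categorical factors (stage, grade,
#' event status) and Student's t-tests for continuous ones (age, survival
#' time). If any balance p-value falls at or below \code{alpha}, the split
#' is redrawn (up to \code{maxRedraws} times, then a hard error).
#'
#' @param clinical data.frame with \code{time}, \code{event} and
#'   optionally \code{stage}, \code{grade}, \code{age} (>= 10 rows).
#' @param trainFraction fraction assigned to training (default 0.5).
#' @param seed integer seed.
#' @param alpha imbalance threshold (default 0.05).
#' @param maxRedraws redraw cap (default 100).
#' @return list: \code{train}, \code{test} (row indices), \code{balance}
#'   (data.frame variable/test/p), \code{attempts}.
#' @export
splitCohort <- function(clinical, trainFraction = 0.5, seed = 1L,
                        alpha = 0.05, maxRedraws = 100) {
    n <- nrow(clinical)
    if (n < 10) stop("need at least 10 records to split")
    nTrain <- round(n * trainFraction)
    set.seed(seed)
    for (attempt in seq_len(maxRedraws)) {
        idx <- sample.int(n, nTrain)
        grp <- factor(ifelse(seq_len(n) %in% idx, "train", "test"))
        bal <- list()
        for (v in intersect(c("stage", "grade", "event"),
                            colnames(clinical))) {
            p <- tryCatch(suppressWarnings(
                stats::chisq.test(table(clinical[[v]], grp))$p.value),
                error = function(e) NA_real_)
            bal[[v]] <- data.frame(variable = v, test = "chi-square", p = p)
        }
        for (v in intersect(c("age", "time"), colnames(clinical))) {
            p <- tryCatch(
                stats::t.test(clinical[[v]] ~ grp)$p.value,
                error = function(e) NA_real_)
            bal[[v]] <- data.frame(variable = v, test = "t-test", p = p)
        }
        bal <- do.call(rbind, bal)
        rownames(bal) <- NULL
        if (all(is.na(bal$p) | bal$p > alpha))
            return(list(train = sort(idx),
                        test = sort(setdiff(seq_len(n), idx)),
                        balance = bal, attempts = attempt))
    }
    stop("no clinically balanced split found in ", maxRedraws, " draws")
}

#' Multivariate Cox model with clinical covariates
#'
#' Joint proportional-hazards fit of the risk-group label together with
#' clinicopathological covariates. Stage and grade are coded as ordinal
#' integers (II/III/IV -> 2/3/4); risk group is 0/1 (high = 1). Collinear
#' covariates are flagged (NA coefficients) with a warning.
#'
#' @param clinical data.frame with \code{time}, \code{event} and the
#'   requested covariates.
#' @param riskGroup "high"/"low" labels aligned to \code{clinical}.
#' @param covariates covariate names among stage, age, grade (default all
#'   present).
#' @return data.frame per covariate: \code{coef}, \code{hr}, \code{lower},
#'   \code{upper}, \code{p}.
#' @export
multivariateCox <- function(clinical, riskGroup,
                            covariates = intersect(
                                c("stage", "age", "grade"),
                                colnames(clinical))) {
    df <- data.frame(time = clinical$time, event = clinical$event)
    if ("stage" %in% covariates) {
        sm <- c(I = 1, II = 2, III = 3, IV = 4)
        st <- clinical$stage
        df$stage <- if (is.numeric(st)) st else unname(sm[as.character(st)])
    }
    if ("age" %in% covariates) df$age <- clinical$age
    if ("grade" %in% covariates) df$grade <- as.numeric(clinical$grade)
    df$risk_group <- as.integer(riskGroup == "high")
    rhs <- setdiff(colnames(df), c("time", "event"))
    fit <- coxph(stats::as.formula(
        paste("Surv(time, event) ~", paste(rhs, collapse = " + "))),
        data = df, ties = "efron")
    b <- stats::coef(fit)
    if (any(is.na(b)))
        warning("collinear covariate(s) flagged: ",
                paste(names(b)[is.na(b)], collapse = ", "))
    se <- sqrt(diag(stats::vcov(fit)))[names(b)]
    data.frame(covariate = names(b), coef = unname(b),
               hr = exp(unname(b)),
               lower = exp(unname(b) - 1.96 * unname(se)),
               upper = exp(unname(b) + 1.96 * unname(se)),
               p = 2 * stats::pnorm(-abs(unname(b) / unname(se))),
               row.names = NULL)
}

#' Apply a frozen risk model to an independent cohort
#'
#' Validation never refits: coefficients are reused as trained. Nodes
#' absent from the validation cohort are tolerated — the score is computed
#' over the available nodes only and the cutoff is rescaled to the median
#' available-node score of the original training samples (kept inside the
#' model), mirroring validation on platforms that measure only part of the
#' signature.
#'
#' @param model a fitted \linkS4class{RiskModel}.
#' @param cohort a \linkS4class{StageCohort} with survival columns.
#' @return list: \code{scores}, \code{group}, \code{logrank} (chisq, p),
#'   \code{reduced} (TRUE if nodes were missing), \code{nodesUsed}.
#' @export
validateExternal <- function(model, cohort) {
    expr <- exprMatrix(cohort)
    avail <- intersect(model@nodes, rownames(expr))
    if (!length(avail))
        stop("no model node measured in the validation cohort")
    reduced <- length(avail) < length(model@nodes)
    sub <- methods::new("RiskModel", nodes = avail,
                        coefficients = model@coefficients[avail],
                        cutoff = 0,
                        trainExpr = model@trainExpr[avail, , drop = FALSE],
                        table = model@table[model@table$node %in% avail, ,
                                            drop = FALSE])
    sub@cutoff <- stats::median(riskScores(sub, sub@trainExpr))
    scores <- riskScores(sub, expr)
    group <- stratifyRisk(sub, expr)
    cl <- clinicalData(cohort)
    lr <- if (length(unique(group)) == 2)
        logrankTest(cl$time, cl$event, group)
    else list(chisq = NA_real_, p = NA_real_)
    list(scores = scores, group = group, logrank = lr,
         reduced = reduced, nodesUsed = avail)
}
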