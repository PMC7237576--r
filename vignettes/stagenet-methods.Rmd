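---
title: "Stage-specific TF–lncRNA network analysis: models and methods"
author: "stagenet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-specific TF-lncRNA network analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stagenet)
```

# The analysis model

`stagenet` treats TF–lncRNA regulation as a two-layer inference problem.
The first layer is *potential* regulation: a TF can regulate a lncRNA if
it has binding evidence — a conserved binding-site interval or a ChIP-seq
peak — inside the lncRNA's promoter. The second layer is *active*
regulation in a biological condition: among potential pairs, those whose
expression is positively correlated within one tumour stage's patients
are called active in that stage. The result is one bipartite network per
stage over a common candidate universe, which makes cross-stage
comparison (overlap counts, activity profiles, specificity scores,
clique dynamics) well-posed.

The key assumptions, stated plainly:

* **Promoter-proximal binding implies potential regulation.** Binding
  evidence is reduced to interval overlap with a fixed window around the
  TSS; distal enhancers, chromatin context and motif affinity are out of
  scope.
* **Positive co-expression is the signature of activation.** The edge
  filter keeps `r > 0` only, so repression is deliberately not modelled
  (mirroring the activation-centred design of stage-specific
  co-expression studies).
* **Stages are exchangeable sample strata.** Correlations are computed
  independently per stage; patients contribute to exactly one stage.
* **Proportional hazards within a cohort.** The risk model is a linear
  Cox score over clique-member expression.

# Candidate edges from binding evidence

The promoter window is 5 kb upstream to 1 kb downstream of the TSS
(`up = 5000`, `down = 1000` bp), strand-aware: upstream means larger
coordinates for a minus-strand gene. Windows come from
`GenomicRanges::promoters()`, so a plus-strand TSS at 1-based position
`t` gives the 1-based window `[t - up, t + down - 1]`, clamped at the
chromosome origin (`restrict(start = 1)`; `trim()` alone is a no-op when
no seqlengths are declared). Any overlap of at least 1 bp between a
TF-labelled interval and any window of a gene creates the candidate edge;
multi-transcript genes contribute the union of their windows. The two
evidence sources are overlapped separately and unioned, with provenance
kept in an `evidence` flag. Conservation filtering is honoured only as an
optional minimum on the BED score column — the package expects
pre-filtered conserved-site tracks.

# Stage networks

For each stage with at least 3 samples, every candidate edge is tested by
Pearson correlation with the two-sided t-test on n − 2 df, and
Benjamini–Hochberg adjustment is applied across all candidates tested
*within that stage* (the per-stage family matches stage-wise edge
reporting; a global family across stages is the obvious alternative and
can be had by pooling, but is not the default). Edges with `r > 0` and
`q < alpha` (default `alpha = 0.05`) are retained.

**Correlation scale.** Correlations are computed on `log2(x + 1)`
expression by default (`transform = "log2"`). RPKM-like values are
heavily right-skewed; on the raw scale the normal-theory t-test for
Pearson's r is strongly anti-conservative far in the tail (in a direct
null simulation with log-normal marginals at n = 60, the nominal p <
0.001 tail fired at ~0.009), which inflates the realised false-discovery
proportion well past the nominal FDR. Log transformation before
correlation is the standard practice for such data and restores
calibration; `transform = "none"` reproduces the raw-scale behaviour for
comparison.

Zero-variance genes make correlation undefined; their candidate edges are
dropped with a warning rather than an error, because a dead gene in a
large matrix should not abort a cohort analysis.

**Topology statistics.** Degree and pair-normalised betweenness
(divided by (N − 1)(N − 2)/2) are delegated to igraph on the undirected
bipartite graph. The topological coefficient is computed from its
definition: for node n with degree e, TC(n) is the average of J(n, m)/e
over all nodes m sharing at least one neighbour with n, where J(n, m) is
the shared-neighbour count plus 1 when n and m are adjacent. In a
bipartite graph, restricting m to direct neighbours would make the
statistic degenerate to 1/degree (neighbours of n share no neighbours
with n), so partners are the distance-2 nodes — the convention of the
Cytoscape NetworkAnalyzer lineage of this statistic. The adjacency bonus
is configurable (`countAdjacent`).

# Activity and specificity

Let x be an edge's per-stage correlation. Within each stage, activities
are z-scored over all edges of the profile universe, z = (x − μ)/σ with
the sample (n − 1) standard deviation, then shifted by the stage minimum
so each stage's activity distribution starts at exactly 0 and stages are
comparable. The universe is every edge significant in at least one stage;
its raw profile keeps the *computed* correlation in the other stages
rather than clamping them to zero, because activity is graded, not a
binary membership (clamping is the documented alternative).

The specificity score of a profile with N stages is

S = Σᵢ (1 − xᵢ/max(x)) / (N − 1),

with negative components clamped to 0 before max-normalisation so that S
stays within [0, 1]: S = 0 iff the profile is constant across stages
(housekeeping-like), S = 1 iff exactly one stage is non-zero. An all-zero
profile has no defined maximum and is excluded with a warning. The
components are the raw (clamped) correlations, not the z-shifted
activities — the score is defined on the quantity that is comparable
across stages before within-stage standardisation. The fraction of edges
with S above 0.15 (`housekeepingFraction()`) summarises how
stage-selective the regulome is; 0.15 is the conventional threshold
separating housekeeping-like from specific profiles.

K-means (`stats::kmeans`, multi-restart, `nstart = 50`
under a fixed seed, default `k = 7` groups) clusters the activity
profiles into archetypes; labels are canonicalised by descending cluster
size so reruns and platforms agree.

# Maximal bicliques

A biclique is a complete bipartite subgraph — every TF regulates every
lncRNA in the module — and is maximal when no node can be added. The
enumerator exploits the bijection between maximal bicliques and *closed*
TF sets (A is closed when A contains exactly the TFs whose neighbourhoods
cover the common lncRNA neighbourhood of A). Closed sets are enumerated
depth-first with prefix-preserving closure extension, so each maximal
biclique is visited exactly once and branches whose common neighbourhood
falls below the lncRNA floor are pruned. An exhaustive brute-force
enumerator over all TF subsets lives only in the test suite, where the
two are compared for exact set equality on random graphs.

Defaults: size floor `minTfs = 2`, `minLncs = 2` (a clique has at least
4 nodes); enumeration runs on the union of edges significant in at least
one stage, because clique dynamics across stages are the object of
interest — a single-stage network can be passed instead. Cliques are
scored by the mean specificity of their edges, sorted descending with
deterministic tie-breaks (larger clique first, then lexicographic id),
and the top `topK = 50` are kept. Their pairwise Jaccard similarity
J(X, Y) = |X ∩ Y| / |X ∪ Y| over pooled node sets (TFs and lncRNAs
together; edge-set Jaccard is the alternative) feeds average-linkage
hierarchical clustering on distance 1 − J, cut at `nClusters = 5`.

# Survival modelling

The cohort is split once into training and testing halves
(`trainFraction = 0.5`). Because a prognostic claim needs the two halves
to be clinically comparable, the split is redrawn (up to 100 times, then
a hard error) until chi-square tests on stage, grade and event status and
t-tests on age and survival time all give p > 0.05.

On the training half, each clique member gets a univariate Cox
coefficient rᵢ (partial likelihood, Efron tie handling — month-resolution
times tie often, and Efron is less biased than Breslow there). The risk
score of a patient is Σᵢ rᵢ·Exp(i); the training median is frozen as the
cutoff, scores strictly above it are "high risk" (ties go to low), and
the cutoff is never recomputed on test data — `stratifyRisk()` only ever
takes the fitted model. Groups are compared by Kaplan–Meier estimates and
the 1-df log-rank test. Multivariate adjustment fits stage (ordinal
II/III/IV → 2/3/4), age, grade (ordinal) and the risk-group indicator
jointly; Wald 95% intervals exp(β ± 1.96·SE) are reported throughout.
External validation applies the frozen coefficients to a second cohort;
when some signature genes are absent there, the score uses the available
members only and the cutoff is rescaled to the available-member median on
the stored training expression, with a `reduced` flag raised.

# The synthetic cohort generator

The generator exists so that every downstream stage has a ground truth.
What it emulates: a staged cohort (default `samplesPerStage = c(II = 20,
III = 60, IV = 30)`, a reduced-scale version of a 20/318/61 staged
ovarian-cancer cohort; the full-size version is exercised in the split
test), a random candidate binding graph (each TF–lncRNA pair drawn with
probability `candidateDensity`), planted stage-specific co-expression,
and survival driven by a planted clique.

* **Expression.** One latent Gaussian per gene and sample, drawn
  independently per stage. A planted edge (tf, lnc, stage, r) makes the
  lncRNA latent a correlated copy of the TF latent with weight r; a
  lncRNA driven by several TFs in a stage gets the weighted sum (weights
  rⱼ, valid while Σrⱼ² < 1, which the config enforces), so each planted
  edge's latent-scale correlation is exactly its target. Latents are
  mapped to `exp(1 + z)` — log-normal, non-negative, right-skewed like
  RPKM. Correlation targets are therefore Gaussian-scale quantities;
  tests check rank correlations, which the monotone transform preserves.
  Planted defaults (r = 0.6–0.8) are engineering choices for a clearly
  detectable but noisy signal.
* **Survival.** Event times are exponential with hazard λ₀·exp(lp),
  lp = Σᵢ βᵢ·Exp(i) over clique members, centred across samples so that
  λ₀ = 0.02 per month sets a realistic median (~35 months). Censoring is
  independent of the event process given the event time: each subject is
  censored with probability `censoringRate` and, if censored, observed at
  a uniform time in (0, T). This hits the requested censoring fraction
  exactly in expectation, which a single global uniform censoring window
  cannot.
* **Annotation files.** One transcript per lncRNA on a toy chromosome
  (alternating strands, loci 100 kb apart so windows never collide), and
  one 50-bp binding interval per candidate edge placed at the centre of
  the target's promoter window, split between the conserved-TFBS and
  peak BED files according to the edge's evidence flag. By construction,
  `findCandidates()` on the emitted files returns exactly the candidate
  graph — the round-trip is asserted inside `runPipeline()` on every run.

What it does **not** emulate: realistic marginal expression distributions
per gene, gene–gene correlation beyond the planted structure, batch
effects, stage-dependent marginals, informative censoring, or real genome
coordinates. Passing tests therefore demonstrate the pipeline's
correctness and calibration under a clean generative model, not
performance on real tumour data.

# Numerical choices and degenerate inputs

* σ in the activity z-score is the sample (n − 1) standard deviation;
  a stage with zero dispersion across edges is a hard error naming the
  stage.
* Negative correlations entering the specificity score are clamped to 0;
  an all-zero profile is excluded with a warning (NA score).
* K-means: 50 restarts, `iter.max = 100`, fixed seed; fewer distinct
  profiles than k triggers a degeneracy warning and a reduced k.
* Biclique ranking ties: mean specificity desc, then size desc, then id.
* Cox fits that fail or do not converge are flagged
  (`converged = FALSE`) and the node excluded with a warning; monotone
  partial likelihoods (perfect separation) take this path.
* Risk-score ties at the cutoff go to the low-risk group.
* Median split on an odd training set puts the median sample in "low".
* Zero-variance predictors, empty stages, non-bipartite inputs, and BED
  records with fewer than 4 fields are hard errors with informative
  messages (the BED error reports the line number).
* Master seed S fans out as: cohort S (graph S, expression S+1,
  survival S+2), K-means S+10, cohort split S+20 — any stage can be rerun
  in isolation with a reproducible stream.

# Problem sizes in the shipped tests

The default pipeline config is 12 TFs × 60 lncRNAs at density 0.25
(~180 candidates) over 110 patients, which runs end-to-end in a few
seconds. Oracle comparisons use 100 random bipartite graphs up to 7 × 7
for biclique enumeration, 50 graphs up to 8 nodes for betweenness and
topological coefficients, 20 cohort replicates of 1,000 candidates with
20 planted edges (r = 0.7, 60 samples/stage) for recovery and FDR
control, 100 replicates at n = 300 for Cox coefficient recovery, and
1,000 null replicates for log-rank calibration. These sizes were chosen
to give stable Monte-Carlo estimates of each property while keeping the
suite quick to run.

# Known limitations

* Repressive (negative-r) regulation is excluded by design.
* The FDR family is per stage; claims about cross-stage edge sets
  aggregate per-stage discoveries without a joint correction.
* Biclique enumeration is exponential in the worst case; it is intended
  for the sparse filtered networks this analysis produces, not dense
  graphs.
* The specificity score depends on the stage count N and is not
  comparable across analyses with different N.
* `validateExternal()` assumes the validation cohort's expression is on
  a scale commensurate with training; no cross-platform renormalisation
  is attempted beyond the reduced-member cutoff rescaling.
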