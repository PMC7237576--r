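# stagenet

Stage-specific transcription factor (TF) – long non-coding RNA (lncRNA)
regulatory network analysis for staged tumour cohorts, with clique-based
prognostic risk modelling.

## What it does, and for whom

Tumour progression reshapes transcriptional regulation: a TF that drives a
lncRNA in one stage may be silent in another. `stagenet` is for
computational biologists who have (a) binding evidence for TFs (conserved
binding-site intervals and/or ChIP-seq peaks), (b) a staged expression
cohort, and (c) clinical follow-up, and who want to ask which TF–lncRNA
regulatory relationships are stage-specific and whether co-regulated
modules predict survival. The package covers the whole path:

1. **Candidate edges** — binding sites and peaks are mapped to each
   lncRNA's promoter window (default 5 kb upstream to 1 kb downstream of
   the TSS, strand-aware); a TF–lncRNA pair supported by either evidence
   source becomes a candidate (`findCandidates()`).
2. **Stage networks** — within each stage, candidates are filtered by
   positive Pearson co-expression (on `log2(x+1)` expression) under
   Benjamini–Hochberg FDR < 0.05, giving one bipartite network per stage
   (`buildStageNetworks()`), plus degree, topological-coefficient and
   betweenness tables and cross-stage Venn overlaps.
3. **Dynamics** — for every edge significant somewhere, its per-stage
   correlation x is z-normalised within stage, z = (x − μ)/σ, and
   min-shifted to give an activity profile; the stage-specificity score

       S = Σᵢ (1 − xᵢ / max(x)) / (N − 1) ∈ [0, 1]

   is 0 for ubiquitous (housekeeping-like) edges and 1 for single-stage
   edges. K-means groups edges into activity archetypes
   (`activityProfiles()`, `clusterActivity()`).
4. **Bicliques** — maximal complete bipartite subgraphs (every TF linked
   to every lncRNA) are enumerated with a closure-based algorithm,
   scored by mean edge specificity, ranked, and clustered by Jaccard
   similarity of their node sets (`enumerateBicliques()`,
   `rankBicliques()`, `clusterCliques()`).
5. **Survival** — for a chosen clique, each member gets a univariate Cox
   coefficient rᵢ on a training half; the per-patient risk score
   Σᵢ rᵢ·Exp(i) is thresholded at the training median to define high/low
   risk groups, compared by Kaplan–Meier curves and log-rank tests on
   training and held-out halves, and adjusted for stage, age and grade in
   a multivariate Cox model (`buildRiskModel()`, `stratifyRisk()`,
   `multivariateCox()`). A frozen model can be applied to an independent
   cohort, tolerating missing signature genes (`validateExternal()`).

A synthetic-cohort generator (`simulateCohort()`) plants stage-specific
co-expression and a survival-driving clique into log-normal,
RPKM-like expression, and emits toy GTF/BED files that round-trip through
the binding-evidence step — so the entire pipeline is testable offline.

## Worked example

```r
library(stagenet)
res <- runPipeline(pipelineConfig(seed = 1L), "out")

res$networks[["III"]]
#> StageNetwork [stage III]: 14 edges, 4 TFs, 11 lncRNAs (182 candidates tested, alpha=0.05)

res$profiles
#> ActivityProfiles: 21 edges x 3 stages
#>   mean specificity: 0.77
#>   activity groups: 7

res$topCliques
#> BicliqueSet: 1 maximal bicliques
#>   node count range: 5 - 5  mean: 5
#>   scored; top mean specificity: 0.894

res$model
#> RiskModel: 5 nodes, cutoff 3.209
#>   node   coef   hr lower upper        p
#> 1  TF1 0.0905 1.09  1.03  1.16 1.90e-03
#> 2  TF2 0.1614 1.18  1.08  1.27 9.29e-05
#> 3 LNC1 0.0967 1.10  1.04  1.17 1.07e-03
#> 4 LNC2 0.2543 1.29  1.15  1.44 7.36e-06
#> 5 LNC3 0.1672 1.18  1.11  1.26 2.17e-07

str(res$survivalTests)
#> List of 2
#>  $ train:List of 2
#>   ..$ chisq: num 27.8
#>   ..$ p    : num 1.34e-07
#>  $ test :List of 2
#>   ..$ chisq: num 28.6
#>   ..$ p    : num 9.02e-08
```

Reading this output: of 182 candidate binding edges, 14 survive the
stage-III co-expression filter; 21 edges are significant in at least one
stage and their mean specificity (0.77) says most are stage-restricted.
One maximal biclique passes the 2 TF × 2 lncRNA floor — the planted
TF1/TF2 × LNC1–3 module, with high mean specificity (0.894). Its
five members all carry positive Cox coefficients (hazard ratios 1.09–1.29
per expression unit); the median-split risk groups separate survival
strongly in both the training half (log-rank p = 1.3e-7) and the held-out
half (p = 9.0e-8), and the high-risk label stays prognostic after
adjusting for stage, age and grade. All tables (per-stage edges, node
metrics, activity profiles, cliques, risk scores, KM curves, manifest)
are written under `out/`.

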