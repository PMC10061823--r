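# m7Gpattern

N7-methylguanosine (m7G) is one of the most prevalent RNA base
modifications; a compact set of ~23 writer/reader/eraser genes (METTL1,
WDR4, the EIF4E family, NCBP1/2, the NUDT hydrolases, ...) regulates it. In
lower-grade glioma, the joint expression of these regulators stratifies
patients into *modification patterns* that differ in prognosis, immune
microenvironment and mutational burden. `m7Gpattern` implements that
analysis end to end for R users working with bulk expression cohorts:
consensus clustering of regulator expression, phenotype-gene screening, a
PCA-based per-sample risk score, survival stratification, single-sample
enrichment for tumor-microenvironment readouts, and mutation/CNV/TMB
summaries — plus a synthetic multi-cohort generator with planted ground
truth so the whole pipeline is testable without external archives.

## The score at the core

Given the phenotype genes that survive a univariate Cox screen
(Wald *p* < 0.05), expression is z-scored per gene and decomposed by SVD.
Each patient *j* receives

&nbsp;&nbsp;&nbsp;&nbsp;m7G score(j) = PC1(j) + PC2(j),

the sum of the sample's projections on the first two principal components,
with each component sign-oriented so that the summed loadings over risk
genes (HR > 1) are non-negative — high score means high risk. Patients are
split at the maximally selected log-rank cutpoint (distinct score values
leaving at least a `minprop` fraction on each side; argmax of the
standardized two-group log-rank statistic).

Around the score sit the standard stages: empirical-Bayes location/scale
batch adjustment across cohorts; resampling consensus clustering
(agglomerative, average linkage, 1 − Pearson distance; 1000 replicates at
80% sample subsampling by default) with CDF/Δ-area/PAC model selection;
the empirical-Bayes moderated t between patterns; ssGSEA (rank-weighted
ECDF statistic, α = 0.25) for hallmark activity and immune/stromal
signature scores; and nonsynonymous mutation frequencies, pairwise
co-mutation (Fisher), and TMB per 38 Mb exome.

## Worked example

```r
library(m7Gpattern)

cfg <- m7gConfig(cohortSizes = c(TCGA = 60, CGGA693 = 50, CGGA325 = 40),
                 nBackground = 110, nPhenotype = 60, nImmune = 20,
                 nStromal = 20, kRange = 2:4, reps = 100, delta = 2)
report <- runAll(cfg, seed = 7)

report$objects$patterns
#> ConsensusResult over k = 2-4 (reps = 100, pItem = 0.80)
#> chosen k = 2; PAC: k2=0.000 k3=0.011 k4=0.024
#> cluster sizes at chosen k: 62/88

report$objects$score
#> ScoreResult: 150 samples, 114 genes
#> score range [-11.730, 13.014]; cutoff 6.99601 (high 40 / low 110)
```

Reading the output: the three simulated cohorts (150 patients) are
log-transformed, batch-adjusted and clustered on the 23 regulators; PAC
(the proportion of ambiguous consensus entries) is 0 at k = 2, so the two
planted patterns are perfectly stable. 146 genes pass the moderated-t
screen between patterns (*p* < 0.05), 114 of them are prognostic in
univariate Cox fits, and their first two principal components yield the
score and its maximally selected cutoff 6.996 (40 high- vs 110 low-score
patients). The headline associations arrive in `report$tables`:

```r
signif(report$tables$score_logrank_p, 3)    # 2.22e-17  high-score group dies faster
signif(report$tables$immune_by_pattern_p, 3) # 1.4e-24  immune-hot pattern
signif(report$tables$tmb_by_group_p, 3)      # 1.08e-13 TMB differs by score group
```

`report$stages` records per-stage status and wall-clock; passing
`outDir =` writes the score table, DEG table, pattern assignments and a
JSON run report. A thin command-line wrapper ships in
`inst/scripts/run_pipeline.R`.

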