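---
title: "Methods: m7G regulator modification patterns, scoring and microenvironment characterization"
author: "m7Gpattern"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: m7G regulator modification patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

N7-methylguanosine (m7G) is an RNA base modification installed at mRNA caps
and internal tRNA/rRNA positions; a compact set of writer, reader and eraser
genes ("m7G regulators") controls it. In lower-grade glioma (LGG), the joint
expression of these regulators defines patient subgroups — modification
patterns — with distinct prognosis, immune microenvironment and mutational
burden. `m7Gpattern` implements that analysis as a reusable pipeline:

1. multi-cohort preprocessing (log transform, merge, empirical-Bayes batch
   adjustment);
2. resampling consensus clustering of regulator expression into patterns;
3. moderated-t differential expression between patterns and a univariate
   Cox screen of the phenotype genes;
4. consensus clustering of the screened genes into gene clusters;
5. a PCA-based per-sample **m7G score** with a maximally selected survival
   cutoff;
6. single-sample gene-set enrichment (ssGSEA) for hallmark-pathway activity
   and immune/stromal (tumor-microenvironment) scores;
7. somatic mutation, copy-number and tumor-mutational-burden summaries and
   the score-response association under immunotherapy labels.

Because the cohorts this design targets (TCGA-LGG and comparable archives)
are external resources, the package ships a synthetic multi-cohort
generator with planted ground truth; every stage is exercised and graded
against that truth.

# Data model

Expression travels as an `M7GExperiment`, a `SummarizedExperiment` subclass
with one `expr` assay (genes x samples), a per-sample `cohort` label and a
unit tag (`raw_tpm` or `log2_tpm1`). Clinical tables are data frames keyed
by `sample_id` with overall survival in days (`os_time`, `os_event`).
`alignSamples()` intersects the two, drops samples with missing survival
status or follow-up below one day, and logs every exclusion by reason.
Gene identifiers are whitespace-trimmed and matched case-sensitively;
silent case-folding would hide curation errors. Duplicate gene rows
collapse to the highest-mean row — a deterministic convention, since the
source archives do not document their own choice among re-sequenced
duplicates. Missing expression cells are an error, not an imputation
target: the intended inputs are complete matrices.

# Preprocessing

`logNormalize()` applies `log2(x + 1)` to TPM-scale values. The order is
fixed as TPM-then-log: inputs are assumed to be TPM already (the archives
distribute TPM/FPKM), and TPM recomputation from counts is out of scope.

`batchAdjust()` removes per-cohort location/scale effects with the
parametric empirical-Bayes model: genes are standardized against an
intercept-only pooled fit, per-(gene, batch) additive effects γ and
variance effects δ² are estimated, shrunk toward normal / inverse-gamma
priors whose hyperparameters come from method-of-moments across genes, and
removed; the coupled posterior equations are iterated to a 1e-6 fixed
point (200 iterations maximum). Afterwards each gene's overall mean and
variance are restored exactly, so the adjustment never relocates a gene,
only reshapes it across batches. Biological covariates are deliberately
not modeled (intercept-only design): the analysis design treats cohort as
the only known nuisance factor. Degenerate inputs: one batch is an error;
a batch of one sample is an error; zero-variance genes pass through
unadjusted with a warning.

A note on what empirical-Bayes adjustment can promise: with a homogeneous
planted shift, the per-gene batch-mean estimates retain sampling noise of
order sd·sqrt(2/n) even after a *perfect* location correction, so
per-gene batch means never match exactly at moderate n. What the procedure
guarantees — and what the tests assert — is that the planted global shift
is removed (the signed mean residual is driven near zero) and that the
output matches the reference ComBat implementation, which the test suite
cross-checks when `sva` is available.

# Consensus clustering

`consensusCluster()` follows the resampling recipe: for each candidate k,
`reps` subsamples of `ceiling(pItem * n)` samples (defaults 1000 and 0.8)
are clustered and the consensus matrix records, for each sample pair, the
co-clustering fraction among co-sampled replicates. The base clusterer is
agglomerative with average linkage on 1 − Pearson correlation between
sample profiles; the published analyses name only the tool and the
resampling parameters, so the base algorithm is this package's decision,
chosen to be deterministic and scale-free. Only samples are resampled;
features are kept.

Model selection reports the consensus CDF, the area under it A(k), the
relative delta area, and PAC — the proportion of consensus entries in the
ambiguous band (0.1, 0.9). The automatic rule minimizes PAC; **exact PAC
ties resolve toward the larger k**, because any merge of stable clusters
is itself stable (three clean blobs give PAC = 0 at both k = 2 and k = 3),
so the finest stable partition carries the information. A `kOverride`
argument reproduces the common practice of fixing k by CDF inspection; the
pipeline fixes k = 2 for the regulator patterns and k = 3 for the gene
clusters, the cluster counts this analysis design targets.

`pcaEmbed()` z-scores genes, decomposes by SVD and orients every component
so its largest-magnitude loading is positive — a deterministic sign
convention so embeddings and downstream scores are reproducible.
Zero-variance genes are excluded with a warning.

# Differential expression and the generic tests

`moderatedT()` is the empirical-Bayes moderated two-sample t: per-gene
pooled variances are shrunk toward a prior variance fitted by method of
moments on the scaled-F distribution of the sample variances (trigamma
inversion, Newton iterations to 1e-10), and the t statistic gains the
prior degrees of freedom. `priorDf = 0` reduces it exactly to the ordinary
pooled t, which the tests exploit as an oracle; the estimated
hyperparameters are cross-checked against `limma::eBayes` when available.
The DEG screen defaults to raw p < 0.05 with no fold-change cutoff
(an FDR threshold is available through `bhAdjust()`); all tests are
two-sided.

`rankTests()` (Wilcoxon with tie and continuity correction, Kruskal-
Wallis), `chiSquare()` (uncorrected Pearson), and `bhAdjust()` delegate to
the standard R implementations behind a validated surface. `spearmanCor()`
computes Pearson correlation of tie-averaged ranks with the
t-approximation p on n − 2 df — the definition itself — because the
default `cor.test` switches approximations in ways that are hard to pin in
a contract. `ddct()` implements 2^(−ΔΔCT) for qPCR relative expression.

# Enrichment and microenvironment scores

`ssgsea()` scores one sample and one gene set as the summed difference
between the rank-weighted in-set ECDF (weight `|rank|^alpha`, default
alpha 0.25) and the unweighted out-of-set ECDF, walked over all genes in
decreasing expression order; ties share average ranks. A set holding only
a sample's top gene telescopes to N/2, which the tests pin as a closed
form. Optional normalization divides the whole matrix by its (max − min),
bounding scores in [−1, 1]. Sets with no overlap are flagged per set
rather than failing the run; a set equal to the whole universe is an
error. The single ssGSEA kernel serves both hallmark-pathway activity and
immune-cell signatures; the kernel-density GSVA variant is intentionally
not duplicated. The "immune score" and "stromal score" of
`estimateScores()` are raw (unnormalized) ssGSEA enrichment of the two
signatures — the ESTIMATE-style reading in which the mesenchymal score is
the stromal signature score. Signature deconvolution (CIBERSORT-family
algorithms) is out of scope.

`ora()` is upper-tail hypergeometric over-representation within a finite
universe with BH adjustment — the GO/KEGG step reduced to its statistic,
with gene-set membership supplied as GMT.

# Survival machinery

Kaplan-Meier curves, log-rank tests and Cox fits delegate to the
`survival` package; ties use Efron's correction (better with heavily tied
survival days). KM display and log-rank default to a 10-year follow-up
restriction (administrative censoring at 3652.5 days); Cox fits use
untruncated times — a documented asymmetry, since the design says nothing
about truncating the regression.

`survCutpoint()` implements the maximally selected log-rank cutpoint: the
candidates are the distinct score values leaving at least
`ceiling(minprop * n)` subjects on each side (default minprop 0.1); each
candidate's standardized two-group log-rank statistic is computed by an
O(n) risk-set sweep, and the argmax of |z| wins, with ties broken toward
the smallest value and samples tied with the cutoff assigned to the low
group (strict inequality defines "high"). No small-sample p-value
correction for the maximal selection is attempted; out-of-sample
validation is the honest check, and the null tests confirm that training
splits do not replicate on independent data.

# The m7G score

`prognosticScreen()` fits a univariate Cox model per candidate gene and
keeps genes with Wald p below 0.05, recording each hazard-ratio direction.
`m7gScore()` then z-scores the kept genes, decomposes by SVD, and assigns
each sample the sum of its projections on components 1 and 2. That reading
of "PC1 + PC2 per sample" is the only one that yields a single score per
patient and matches how this score family is used in the antecedent
signature literature. Because principal-component signs are arbitrary,
each component is oriented so the summed loadings over risk genes
(HR > 1) are non-negative — high score then means high risk, anchored to
the direction in which the low-score group shows the survival benefit.
With no risk genes the orientation flips to make protective loadings
non-positive. `stratify()` applies `survCutpoint()` and attaches groups,
KM curves and the log-rank test. The published meta-cohort cutoff
1.530208 is a reference value from the original external cohorts; it is
not reproducible from synthetic data and is not used anywhere as a
constant.

`responseAssociation()` compares scores between CR/PR and SD/PD
(two-sided Wilcoxon) and tests the score-group by response table
(chi-square; a table with all samples in one score group is a zero-
marginal error). `scoreGroupCrosstab()` cross-tabulates any two
assignments with Cramér's V and, when scores are supplied, a
Kruskal-Wallis test of score by cluster.

# Alterations

"Mutated" means at least one nonsynonymous record under a declared
MAF-style vocabulary (`variantClassLookup()`); classes outside the
vocabulary are warned about and treated as synonymous. Frequencies are
percentages of the full cohort with absent samples counted as unmutated.
TMB divides each sample's nonsynonymous record count by a 38 Mb exome
footprint — the denominator is a config knob, since the source analyses
never define their TMB formula. Pairwise co-mutation uses the two-sided
Fisher exact test with BH adjustment and a phi coefficient alongside.
When a TMB survival split is wanted, the same `survCutpoint()` machinery
is applied to TMB and the chosen threshold recorded, since no fixed
high/low TMB threshold is published for this design.

# The synthetic generator

`simulateMetaCohort()` emulates the structure of a three-cohort LGG
meta-cohort; its defaults are the study conditions the tests run under:

- cohort sizes 490/330/160 (the scale of the archives this design
  analyzes), configurable down to test scale;
- two regulator patterns: pattern A receives +δ and pattern B −δ per
  gene (random per-gene sign), δ = 1.5 log2-units by default, unit noise;
  pattern A has prior probability 0.62, the approximate published split;
- a latent risk L = standardized pattern effect (+1 coding for pattern B)
  plus N(0, 0.5) noise; phenotype genes load on L with signed weights
  drawn from ±U(0.8, 1.2) and carry a three-block structure tied to the
  true gene-cluster label (tertiles of a noisy copy of L), so gene
  clusters are both real and risk-ordered — cluster C is the high-risk,
  high-score cluster;
- survival: exponential with hazard λ0·exp(β·L), β = 0.9, baseline
  median about three years, under uniform administrative censoring on
  [0, 10 years]; times are rounded up to whole days so every subject
  survives at least one day;
- immune signature genes elevated by 1.0 in pattern B and stromal genes
  by 0.5 (pattern B is the immune-hot, high-risk pattern); eleven
  hallmark-style sets of background genes carry a mild 0.4 loading on L;
- per-cohort additive offsets (default centered around 0, one unit apart)
  and multiplicative noise scaling on the log2 scale, applied before the
  matrix is exponentiated back to the TPM scale;
- mutation counts Poisson with mean 5 (pattern A) vs 20 (pattern B) over
  a mixed variant-class vocabulary, CNV states per regulator with
  gene-specific gain/loss propensities, and therapy response
  CR/PR vs SD/PD drawn with logit a − b·L (b = 1.5): high-risk patients
  respond less, the direction seen in the anti-PD-L1 setting.

Randomness is hierarchical: one master seed derives a gene-parameter
substream and one substream per cohort, so resizing a cohort never
perturbs the others and everything is reproducible bit-for-bit.

What the generator does *not* emulate — and therefore what green tests do
not certify about real data: negative-binomial read-count noise,
gene-gene correlation beyond the planted factors, informative censoring,
copy-number segmentation, or realistic mutation hotspots. Passing tests
show the machinery recovers planted structure at realistic effect sizes;
they do not validate the biology of any external cohort.

# Problem sizes and numerical choices

The test suite and the acceptance script run at deliberately moderate
sizes, chosen as the package's own benchmark conditions: meta-cohorts of
150-400 samples with 200-300 genes, 50-200 consensus replicates for unit
checks, Cox recovery at n = 2000 over 10 seeds, and 1000-replicate null
simulations for the type-I checks. Key numeric conventions: trigamma
inversion and the EB fixed point iterate to 1e-10/1e-6; PCA and score
equivalences are asserted at 1e-8 against independent eigendecompositions;
consensus matrices, KM curves and BH adjustments are asserted at 1e-9 to
1e-12 against enumeration oracles; p-values are two-sided everywhere; all
pipeline randomness flows from one integer seed kept below 2^31.

# Limitations

The score's sign orientation needs at least one screened gene with a
defined hazard direction; a screen that keeps nothing degrades to a
warning and an empty gene list. The maximally selected cutpoint inherits
selection optimism on its training split. The hypergeometric ORA ignores
the GO DAG. IC50 imputation, docking, hub-gene mining against external
databases, and figure rendering are out of scope; the tables behind such
figures are produced, the graphics are not.
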