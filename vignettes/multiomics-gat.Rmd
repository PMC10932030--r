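---
title: "Multi-omics integration with graph attention networks: models and methods"
author: "gatfuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-omics integration with graph attention networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Cancer subtypes (e.g. the five intrinsic breast-cancer subtypes Basal,
HER2-enriched, Luminal A, Luminal B and Normal-like) differ in prognosis
and treatment response, and no single molecular layer identifies them
perfectly. `gatfuse` integrates up to eight patient-level data layers —
clinical covariates (CLI), copy number alteration (CNA), co-expression
module eigengenes (COE), mRNA (EXP), lncRNA (LNC) and miRNA (MIR)
expression, DNA methylation (MET) and binary somatic mutation (MUT) —
into per-patient embeddings that are then used for subtype classification
and survival risk stratification.

The working hypothesis is that patients similar in a given omics layer
tend to share a subtype, but that not all neighbors in a patient
similarity network are equally informative. A graph attention network
(GAT) learns *how much* each neighbor should contribute, rather than
averaging neighbors with fixed weights as a graph convolutional network
does.

# The model

## Patient similarity networks

For each omics layer a patient-by-patient similarity matrix is computed
with a metric matched to the data type:

* **Pearson correlation** between feature vectors for the continuous
  layers (EXP, LNC, MIR, MET, CNA, COE). Raw signed correlation is used
  for ranking: the highest correlation is the most similar patient.
* **Jaccard similarity** (shared mutated genes over the union) for the
  binary MUT layer.
* **Gower similarity** for the mixed continuous/categorical clinical
  table: per-attribute scores (range-scaled distance complements for
  continuous attributes, exact-match indicators for categorical ones)
  averaged over the attributes observed in both patients. Gower is
  computed on the raw clinical table; the one-hot encoding is used only
  for node features.

Each patient is then linked to its `k = 3` most similar other patients
(deterministic tie-break by ascending sample ID), and the directed pairs
are symmetrised by union into an undirected graph. Under union
symmetrisation the edge count lies in `[ceil(3n/2), 3n]`, the regime
observed in real cohorts of this design.

## Graph attention layers

Let `x_i` be the node feature vector of patient *i* (the concatenation of
all selected, normalised features across the available omics layers —
every per-omics GAT sees the same feature matrix but its own graph). One
attention head with parameters `W` (p x m) and `a = [a_self; a_neigh]`
(2p) computes, for every neighbor `j` of `i` (self-loop included):

* raw scores `c_ij = LeakyReLU(a' [W x_i || W x_j])`, negative slope 0.2;
* normalised coefficients `alpha_ij = softmax_j(c_ij)` over the
  neighborhood `N_i` (computed with max subtraction, so `sum_j alpha_ij = 1`
  to machine precision);
* the aggregated representation `h_i = sigma( sum_{j in N_i} alpha_ij W x_j )`.

Two design points deserve a note. First, self-loops are added to every
neighborhood: they guarantee non-empty neighborhoods and let a node
retain its own signal. Second, the aggregation sums `alpha_ij W x_j` over
neighbors `j`, the form of the original GAT literature. A degenerate
variant that sums `alpha_ij W x_i` collapses to `h_i = W x_i` for *any*
attention weights (the coefficients sum to one), which would make
attention vacuous; `gatfuse` deliberately implements the non-degenerate
form.

The architecture is two layers: layer 1 uses `H` heads of width
`hidden_dim / H`, ELU activation, outputs concatenated; layer 2 uses `H`
heads of width equal to the number of subtypes, averaged, with no
nonlinearity before the softmax. The layer-1 hidden representation (width
`hidden_dim`, default 512) is the per-omics patient embedding.

## Training

Each per-omics GAT is trained full-batch with Adam as a supervised node
classifier on subtype labels (cross-entropy on training nodes). The
per-omics training objective is a genuinely open design point in this
family of frameworks; supervised node classification is the convention of
the graph-based integration methods this package follows. Splits are
stratified 70/10/20 train/validation/test by subtype and resampled for
each of the (default ten) repeated runs — resampling gives a more
conservative variance estimate than refitting one fixed split.

Model selection keeps the epoch with the best validation macro-F1, and
training stops early once the validation macro-F1 has not improved for
`patience` epochs (default 40) or cannot improve further; the epoch cap
(default 200) and the learning rate (0.001), hidden width (512) and head
count (1) defaults are the grid-search optima for this architecture.
`train_gat(grid = ...)` searches a Cartesian grid (hidden 128–1024,
learning rate 1e-4–1e-2, 100–500 epochs, 1–8 heads) by validation
macro-F1 when tuning is wanted; it is per-omics by default.

## Fusion and classification

Per-omics embeddings are concatenated column-wise in a canonical
(alphabetical) omics order and fed to a dense MLP (default hidden layers
(64, 32), learning rate 0.001, up to 1000 epochs, same
best-validation-epoch selection). `run_combination_sweep()` evaluates
every non-empty omics subset (2^T − 1 of them) or the leave-one-omics-out
ablation, with fresh stratified splits per run; metrics (accuracy,
weighted-F1, macro-F1) are computed on test nodes only. A randomized
hyperparameter search (`train_mlp(search_budget = 20)`) is available but
the sweep default uses the fixed optimum configuration — a per-subset,
per-run search multiplies runtime twentyfold without changing what the
sweep measures on these cohorts.

To avoid test-set leakage, label-aware feature selection (below) is
re-fit inside every run on train+validation nodes only; test nodes never
influence selection or model choice. Z-scoring and graph construction are
whole-cohort operations, consistent with the transductive setting (all
nodes, labelled or not, participate in message passing).

## Preprocessing rules

* **Expression filters**: features are kept when the raw-scale value is
  at least 1 in at least 15% of samples (FPKM, mRNA/lncRNA) or 30% of
  samples (RPM, miRNA). Filtering operates on the raw nonnegative scale
  before normalisation, and is idempotent.
* **Duplicate samples** from one patient merge by per-feature mean
  (continuous layers) or Boolean OR (mutation); clinical duplicates are
  resolved upstream by keeping the first record.
* **Clinical encoding**: categorical attributes one-hot encode (with an
  explicit `<missing>` indicator when needed); age and other continuous
  attributes pass through unscaled.
* **Common samples**: all layers, labels and survival tables are
  restricted to the intersection of sample IDs, in a shared sorted order;
  alignment is always by ID, never by position.
* **Feature selection**: a label-aware univariate ANOVA-F ranking with a
  deterministic feature-ID tie-break stands in for heavier external
  selectors (random-forest wrappers, differential-expression pipelines);
  the scoring function is pluggable (`select_features(score_fn = ...)`)
  so any ranking can be substituted. Defaults keep 1000 features for
  EXP/MET, 500 for CNA/LNC and 200 for MUT, mirroring the dimensionality
  profile such cohorts use; layers already low-dimensional (COE, MIR,
  CLI) are not reduced.
* **Normalisation**: z-score per feature for CNA/EXP/LNC/MIR/MET
  (zero-variance features map to zeros, keeping downstream algebra
  finite); MUT (binary), CLI (one-hot) and COE (eigengenes) are used
  unnormalised.

## Survival evaluation

The survival pipeline asks whether embeddings that capture subtype also
stratify risk. On a feature matrix (raw fused features or fused
embeddings):

1. **LASSO** linear regression of the *observed* follow-up time on the
   predictors, penalty chosen by cross-validated grid search over
   {0.001, 0.002, 0.005, 0.01, 0.05, 1.0}; nonzero-coefficient predictors
   are kept. Regressing observed time ignores censoring at the selection
   stage — this reproduces the stated protocol of the frameworks this
   package follows, and is statistically questionable; censoring is
   honoured from the Cox stage onward. A penalised-Cox selector would be
   a natural alternative behind the same interface.
2. **Multivariate Cox proportional hazards** on the selected predictors
   (Breslow tie handling), giving coefficients (log hazard ratios) and
   Wald p-values.
3. **Risk score** `sum_i X_i * Coef_i` over the predictors significant at
   p < 0.05 (threshold exposed as a flag).
4. **Median split**: score less than or equal to the median is low-risk —
   ties go to the low-risk group by definition.
5. **Kaplan-Meier** curves per group, the two-group **log-rank test**,
   and the **hazard ratio** (high vs low risk) from a univariate Cox fit
   on the group indicator.

`compare_feature_sets()` runs the whole chain independently on raw
features and on embeddings and reports both log-rank p-values; an arm
where no predictor survives selection or significance yields `NA` (it
cannot stratify) rather than aborting the comparison.

# The synthetic cohort generator

`synthetic_spec()` / `generate_multiomics_cohort()` emulate the study
conditions every stage is tested under:

* subtype proportions default to a five-subtype breast-cancer cohort
  profile (Basal 17.24%, HER2 8.02%, LumA 50.65%, LumB 20.39%,
  Normal-like 3.68%);
* continuous layers are standard Gaussian within subtype, with an
  informative fraction (default 20%) of features shifted per subtype by
  `effect_size` (default 3) standard deviations along fixed unit-Gaussian
  directions, so `effect_size = 0` is an exact null and separation is
  monotone in the effect size;
* EXP/LNC/MIR additionally get a log-normal raw-scale variant
  (FPKM/RPM-like) so the expression filters operate on realistic input;
* MUT features are Bernoulli (baseline rate 0.05) with subtype-dependent
  rates on the logit scale for the informative fraction;
* the clinical table has age plus three categorical attributes whose
  category frequencies depend on subtype in proportion to `effect_size`
  (so the null cohort is null in the clinical layer too);
* survival times are exponential with per-subtype log hazards. The
  defaults are a clinical-prognosis ordering (Basal worst, Luminal A
  best, a +0.5 to −0.5 log-hazard spread) around a baseline chosen so
  mean survival falls between ~3.6 and ~9.9 years. Follow-up times on a
  realistic year scale matter because the LASSO penalty grid of the
  survival protocol is in absolute units: on much larger time scales its
  strongest penalty cannot shrink a pure-noise fit to zero, and on much
  smaller scales it shrinks everything. Censoring is an independent
  Uniform(0, b) time with `b` calibrated numerically to hit the target
  censoring rate (default 0.3).

Default problem sizes are chosen for a cohort that one CPU handles in
minutes: n = 400 patients, four layers (CLI, EXP, MET, MUT), 300/200/150
features for EXP/MET/MUT. What the generator does *not* emulate: real
marginal distributions (FPKM tails, CpG beta bimodality), batch and
platform artifacts, correlated feature blocks beyond the subtype
structure, across-omics missingness patterns, and feature-level (rather
than subtype-level) hazard effects. Passing tests therefore demonstrate
correctness of the machinery and recoverability of planted structure, not
performance on real cohorts.

# Numerical choices

* Softmax normalisation subtracts the per-neighborhood maximum before
  exponentiation (overflow-safe).
* Zero-variance features z-score to zeros; zero-variance similarity rows
  get similarity 0 with a warning; two all-zero mutation profiles have
  Jaccard similarity 0 by convention.
* Top-k neighbor ties break by ascending sample ID, making graphs
  reproducible across platforms.
* Cox fits stop at a relative Newton step below the `survival` package
  default (or 100 iterations); non-convergence, monotone likelihood and
  singular information are reported as errors naming the offending
  predictors.
* All randomness flows through R's RNG from a single seed per run; a
  fixed seed reproduces metric tables byte for byte, and the run manifest
  records every parameter.

# Known limitations

* The per-omics GAT objective is supervised; an unsupervised variant
  would be needed when labels are unavailable.
* Full-batch dense training targets cohorts of a few thousand patients;
  no mini-batching or neighbor sampling is provided.
* The LASSO stage regresses observed time (see above).
* Embedding export is provided for visualisation, but no ordination
  plotting is built in.
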