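# gatfuse

Multi-omics integration with graph attention networks (GATs) for cancer
subtype prediction and survival risk stratification.

## What it does, and for whom

Molecular subtypes of cancer (e.g. the five intrinsic breast-cancer
subtypes) are easier to recover when several omics layers are combined.
`gatfuse` is for computational biologists who have patient-level
sample-by-feature matrices for up to eight layers — clinical (CLI), copy
number (CNA), co-expression eigengenes (COE), mRNA/lncRNA/miRNA
expression (EXP/LNC/MIR), DNA methylation (MET), binary mutation (MUT) —
plus subtype labels and, optionally, survival outcomes.

For every layer the package builds a **patient similarity network**
(Pearson correlation for continuous layers, Jaccard for mutations, Gower
for mixed clinical data; each patient linked to its top *k* = 3
neighbors) and trains a two-layer **graph attention network** as a
subtype node classifier. One attention head computes, for each neighbor
*j* of patient *i* (self-loop included),

    c_ij    = LeakyReLU( a' [W x_i || W x_j] )        (raw attention, slope 0.2)
    alpha_ij = exp(c_ij) / sum_{k in N_i} exp(c_ik)    (softmax per neighborhood)
    h_i     = sigma( sum_{j in N_i} alpha_ij W x_j )   (weighted aggregation)

so each patient learns *how much* to listen to each neighbor instead of
averaging them equally as a GCN would. The layer-1 hidden representations
(default width 512) are per-omics patient **embeddings**; they are
concatenated across layers and classified by an MLP, with repeated
stratified runs, full 2^T − 1 omics-combination sweeps and
leave-one-omics-out ablations (accuracy, weighted-F1, macro-F1).

Embeddings are also evaluated by a **survival pipeline**: LASSO selection
against observed survival time, multivariate Cox proportional hazards,
risk score = Σ X_i·Coef_i over predictors with p < 0.05, median split
into low/high risk, Kaplan–Meier curves, log-rank test and hazard ratio —
run side by side on raw features and on embeddings.

A synthetic-cohort generator with known subtype structure and
subtype-dependent hazards makes the whole pipeline testable without any
external data.

## Worked example

```r
library(gatfuse)

cfg <- default_config()          # k = 3, GAT 512/0.001/200 epochs, MLP (64,32)
cfg$runs <- 2L                   # two repeated runs for a quick look
cfg$seed <- 42L

res <- run_pipeline(cfg, outdir = "demo_out",
                    combinations = list(c("CLI", "EXP", "MET", "MUT")),
                    verbose = FALSE)
res$summary[, c("combination", "macro_f1_mean", "macro_f1_sd")]
#>       combination macro_f1_mean macro_f1_sd
#> 1 CLI+EXP+MET+MUT             1           0

str(res$survival$p_values)
#> List of 2
#>  $ raw       : num 4.94e-09
#>  $ embeddings: num 4.18e-08
```

This synthesizes the default cohort (400 patients, 5 subtypes with
realistic imbalance, subtype effect size 3 SD on 20% of features, four
omics layers), trains one GAT per layer per run, fuses the embeddings and
classifies subtypes. The test macro-F1 of 1 on held-out patients says the
fused embeddings recover the planted subtypes perfectly at this effect
size; the survival stage shows both raw features and embeddings separate
low-/high-risk groups very significantly (subtype drives hazard in the
generator, and at effect size 3 the raw features carry that signal
directly). `demo_out/` contains the per-layer graphs and embeddings (TSV),
sweep metrics, risk tables, KM curves and a `manifest.json` recording
every parameter and seed; rerunning with the same seed reproduces every
number byte for byte.

A thin command-line front end is included:

```sh
Rscript inst/cli/gatfuse.R run --seed 1 --outdir out/
Rscript inst/cli/gatfuse.R synth --seed 1 --outdir cohort/
Rscript inst/cli/gatfuse.R graph --features cohort/EXP.tsv --omics EXP --k 3 --out edges.tsv
Rscript inst/cli/gatfuse.R survival --features cohort/EXP.tsv --survival cohort/survival.tsv --out report.json
```

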