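# mbcoin: multi-block co-inertia integration of multi-omics cohorts

`mbcoin` implements an end-to-end, unsupervised multi-omics integration
pipeline for case/control classification, of the kind used to separate
relapsing-remitting multiple sclerosis (RRMS) from neurological disease
controls using small-RNA profiles from plasma, PBMCs, CSF cells and
cell-free CSF together with a CSF-cell methylome. It is aimed at
bioinformaticians who have several feature matrices (blocks) measured on
the same individuals — counts with wildly different library sizes, beta
values in [0, 1], feature counts spanning orders of magnitude — and who
want a shared latent variable that classifies a phenotype, plus a short,
interpretable feature list.

## The method

**Multiple co-inertia analysis (MCIA).** Each preprocessed block
X_k (samples × features) is column-centered, scaled by the per-feature
standard deviation, and divided by the square root of its total sum of
squares, so every block enters with unit inertia. Components are extracted
iteratively from the concatenated matrix X = [X_1 X_2 … X_K]: the leading
singular triplet (u, d, v) gives the *global latent score* t = u·d; the
right singular vector is split into block segments and each segment is
renormalized to a unit-norm *block loading* v_k; each block is then
deflated by the rank-1 projection onto its own loading,
X_k ← X_k(I − v_k v_kᵀ) ("blockLoading" deflation), which makes loadings of
successive components orthogonal within every block. Block contributions
to component j are c_kj = ((t_kjᵀ t_j)/(t_jᵀ t_j))² · (t_jᵀ t_j) with t_kj
the partial (block) score; held-out samples are projected by standardizing
them with the *training* parameters and multiplying by the concatenated
loading matrix.

**Evaluation.** Each latent variable is scored against the diagnosis
labels without a probabilistic classifier: an exact two-cluster 1-D
k-means partition is deformed by relocating, one sample at a time, the
sample whose move changes the k-means objective least, tracing out
(FPR, TPR) points whose trapezoid area is the AUROC; partition agreement
is additionally measured by the split-join distance.

**Feature reduction.** The component-1 global score is regressed on the
concatenated features with an L1 penalty (5-fold cross-validated λ);
features with β = 0 are dropped, blocks losing all features leave the
model, and the decomposition is refit on the reduced feature set.

Per-assay preprocessing follows the conventions of small-RNA and
methylome studies: a minimum-total-UMI filter (≥ 100) and TMM/CPM
normalization for Small-seq counts, a two-thirds group-coverage filter
for MINTmap tRF counts, and a robust-coefficient-of-variation filter
(RCV = median(|x − median(x)|)/median(x) ≥ 1) for smoothed methylation
beta values.

## Worked example

A synthetic five-block cohort with a planted group-separating factor
(20 RRMS, 14 controls, 6 held-out progressive samples; ~2000 features;
factor loadings deliberately weak in the PBMC and methylome blocks):

```r
library(mbcoin)
cfg <- pipelineConfig(synthetic = syntheticConfig(seed = 1),
    nComponents = 10, seedCV = 2L)
rep <- runPipeline(cfg)
print(rep)
#> RunReport
#>   features in full model: 1101
#>   best component: L1 (AUC 0.968, split-join 14)
#>   reduced model: 19 features, AUC 0.889, split-join 14
#>   full-vs-reduced rank correlation: 0.158
round(rep$contributions[, 1, drop = FALSE], 3)
#>                        L1
#> pbmc_smallseq       0.119
#> plasma_smallseq     0.236
#> csf_cells_smallseq  0.183
#> csf_free_mintmap    0.316
#> csf_cells_methylome 0.146
```

1101 of 2000 simulated features survive the per-assay filters; the first
latent variable separates cases from controls with AUROC 0.968 and is
flagged best of the ten; the Lasso reduces the model to 19 features with
a modest AUROC drop (0.889); and the contribution table shows the planted
pattern — the PBMC and methylome blocks carry the least of L1. Group
rank-sum tests on L1 (in `rep$groupTests`) separate positives from
controls (p ≈ 5e-06) while relapse/remission and the two control
subgroups do not differ, and the projected held-out group lands between
cases and controls.

A small pre-generated cohort ships in
`inst/extdata/example_cohort/` (readable with `readCohort()`), and
`inst/scripts/mbcoin-pipeline.R` is a thin command-line wrapper with
`simulate` and `run` subcommands.

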