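---
title: "Multi-block co-inertia integration: model, choices, and limits"
author: "mbcoin authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-block co-inertia integration: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbcoin)
```

## The problem and the model

Cohort studies of multiple sclerosis (and of many other diseases)
increasingly profile the same individuals across several molecular layers
and body compartments at once: small-RNA counts from plasma, PBMCs, CSF
cells and cell-free CSF, and a DNA-methylation profile of CSF cells. Each
of these *blocks* is a samples × features matrix with its own units,
noise model and feature count — from a few hundred tRNA fragments to
over a hundred thousand CpG sites. The question `mbcoin` answers is
whether a *shared* axis of variation across these blocks separates a
clinical phenotype (here: relapsing-remitting MS plus isolated syndromes
versus neurological disease controls), how much each block contributes to
that axis, and how few features suffice to retain it.

Multiple co-inertia analysis (MCIA) is the multi-block latent-variable
decomposition used for this. Its working assumptions are worth stating
plainly:

* the phenotype-relevant structure is **shared** across blocks — MCIA's
  covariance objective rewards directions on which several blocks agree;
* each feature's information is adequately captured **linearly** after
  per-feature standardization (hence the variance-stabilizing log
  transform of normalized counts);
* blocks should compete on **equal footing** regardless of size, which
  the unit-inertia scaling enforces: a 143,000-feature methylome cannot
  dominate a 250-feature tRF panel by feature count alone, only by
  carrying coherent structure.

The fitted object separates three kinds of quantities: *global scores*
(one coordinate per sample and component, the classification axis),
*block loadings* (unit vectors per block, the interpretable feature
weights), and *partial scores* (each block's own view of a component,
whose alignment with the global score defines the block's contribution).

## Parameters that matter

| parameter | default | meaning and rationale |
|---|---|---|
| `minTotal` | 100 | minimum summed UMI count per Small-seq feature across samples; removes features too sparse to normalize stably. Boundary inclusive: exactly 100 is kept. |
| `coverageFraction` | 2/3 | fraction of samples (per diagnosis group) in which a tRF feature must be detected; with `coverageMode = "both"` the feature must reach it in *both* groups. |
| `rcvThreshold` | 1 | robust coefficient of variation, median(|x − median|)/median, unitless; retains only highly variable methylation sites. |
| `mTrim`, `aTrim` | 0.30, 0.05 | TMM trim fractions on log-ratios and intensities — the published defaults of the method; only the method name, not the trims, is usually reported. |
| `logTransform` | TRUE | log2(CPM + 1) before standardization; whether the original analyses log-transformed is typically unstated, so it is a switch. |
| `inertia` | "root" | divide standardized blocks by the square root of the total sum of squares (unit inertia). The raw-sum variant is available; the two differ only by per-block scale factors. |
| `nComponents` | 10 | latent variables extracted and evaluated (L1–L10); L1 carries the most variance by construction. |
| `folds`, `lambdaRule` | 5, "min" | cross-validation folds (stratified by label) and penalty rule for the Lasso. `lambda.min` favours discriminative retention; `"1se"` gives sparser models. |
| `sdFilter` | FALSE | optional post-selection filter keeping features with \|β\| above 1 SD of the nonzero-\|β\| distribution. The phrase it operationalizes is ambiguous in common usage, so it is off by default rather than guessed into the defaults. |

## Numerical and design choices

**Column scaling.** Standard deviations use the n−1 denominator
throughout. Note that the choice is immaterial for the decomposition: a
uniform rescaling of all columns is absorbed by the inertia divisor.

**Deflation.** The per-component update is the rank-1 residual
X_k ← X_k(I − v_k v_kᵀ) with unit v_k ("blockLoading" deflation). A
formulation sometimes written as X_k − X_k·V_kᵀ is dimensionally
inconsistent and is not used. Block-loading deflation guarantees (i)
within-block orthogonality of loadings across components, (ii)
non-increasing eigenvalues, and (iii) that projection with the raw
concatenated singular vectors reproduces the fitted scores exactly.

**Block rank exhaustion.** A block with p_k features supports at most
p_k deflations; afterwards its loading segment is numerical noise. Such
blocks receive exactly zero loadings and partial scores on later
components (threshold: segment norm ≤ 1e−8) rather than a normalized
noise vector.

**Solver.** The leading triplet is computed by dense SVD per component —
at cohort scale (tens of samples, thousands of features) this is fast and
has no convergence parameters. A NIPALS-style power iteration
(`solver = "power"`, tol 1e−9, maxiter 1000) is retained for very wide
data.

**Sign convention.** Each component is flipped so its largest-magnitude
concatenated loading is positive, making reports reproducible across
platforms.

**Projection.** Held-out samples are standardized with the *training*
column means, SDs and inertia divisor — never pooled statistics — and
their TMM factors are computed pairwise against the training reference
sample in a separate pass, so the training output is bitwise independent
of whether held-out samples are present. Samples sitting exactly at the
training feature means project to zero on every component.

**Relocation AUROC.** The 1-D two-cluster k-means is solved exactly by
enumerating the n−1 sorted splits (no random initialization, no seed).
During the relocation sweeps, cluster means are recomputed after every
move, candidate ties are broken by the smaller sample index, and the
final curve merges both sweeps' point sets with (0,0) and (1,1). The
true-positive cluster is fixed once, at the initial partition; when the
initial cluster table is exactly tied the rule falls to cluster 2, the
one configuration in which the direction choice is not sign-invariant.
Because the designation picks the label-favoured direction, the metric's
chance level at small n sits slightly above 0.5 (about 0.58 at 15 + 15),
a property the test suite measures rather than hides.

**Group coverage semantics.** "Filtered out when covered by less than
2/3 of samples in either group" is read literally: failure in at least
one group removes the feature, i.e. keeping requires both groups to reach
the fraction. The one-group-suffices alternative is
`coverageMode = "either"`.

**Robust CV.** The printed form of the robust coefficient of variation
omits the absolute value, which would make it negative for half the
data; the conventional MAD/median (with absolute deviations) is
implemented. Features with median 0 have undefined RCV and are excluded
with a logged reason rather than an error.

**Rank-sum tests.** Group comparisons on latent scores use the unpaired
two-sample rank-sum (Mann-Whitney) test — the groups are independent, so
a signed-rank (paired) test would be inapplicable despite occasionally
appearing in figure legends of this literature. Exact enumeration is used
up to pooled n = 12 without ties; otherwise the tie- and
continuity-corrected normal approximation.

**Reduced-model refit.** After selection, blocks are restricted to the
selected features, empty blocks dropped, and only *restandardization* and
refitting are redone — the per-assay filters and normalization are not
recomputed on the reduced feature set.

## What the synthetic cohorts emulate — and what they do not

`syntheticConfig()` encodes the study conditions the pipeline was
designed around: a positive group (RRMS, split into relapse/remission
phases), a mixed control group (NINDC/INDC), and a held-out progressive
group generated for projection only; five blocks with very different
feature counts; overdispersed negative-binomial counts on a log-linear
mean model with log-normal library-size variation (CV 0.5, NB size 2);
and a beta-distributed methylome whose baseline is bimodal — a stable,
high-precision high-methylation background that the RCV filter removes
wholesale (as it does for real smoothed methylomes) and a low,
highly variable mode where the differential signal lives. One shared
latent factor drives all blocks, with strong loadings (0.8) in the
plasma, CSF-cell and cell-free-CSF small-RNA blocks and deliberately
weak loadings (0.2) in the PBMC and methylome blocks, mirroring the
contribution pattern such cohorts show. The held-out group's factor mean
sits halfway between cases and controls by default
(`progressiveShift = 0.5`). The default cohort sizes (20/14/6) match a
realistic single-centre cohort; effect size 2 (in within-group factor SD
units) and a 10% informative-feature fraction were chosen once as
realistic for a separable but imperfect biomarker signal.

What passing tests on these cohorts show: the decomposition recovers a
genuinely shared factor against structured per-block noise, filters
behave sensibly on realistic marginals, selection is enriched for truly
informative features, and the evaluation machinery is calibrated. What
they do not show: robustness to batch effects, to per-block (unshared)
confounding factors, to missing samples in some blocks, or to the
read-level artifacts of the upstream pipelines (adapter content,
bisulfite conversion, mapping multiplicity) — none of which are
simulated. Effect sizes estimated on synthetic cohorts say nothing about
real-data effect sizes.

Test and acceptance runs use scaled-down problem sizes chosen as the
smallest that exercise every code path meaningfully: cohorts of 15 + 15
fitting samples with ~2,000 raw features across five blocks for the
recovery runs, 6–10-sample instances for the oracle equivalences.

## Known limitations

* The relocation AUROC is a descriptive in-sample measure; it is not
  cross-validated, and its small-sample chance level is above 0.5 (see
  above), so values near 0.5–0.6 should be read as "no signal".
* Blocks must share the complete sample set; there is no missing-block
  or missing-sample imputation.
* Consensus-PCA variants other than blockLoading deflation, kernelized
  extensions, and group/elastic-net penalties are out of scope.
* With only tens of samples, the Lasso's selected set is unstable across
  CV fold assignments; the fold seed is therefore recorded in every
  result, and rank comparisons between full and reduced models are
  reported over the selected features only.
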