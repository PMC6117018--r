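---
title: "Benchmarking batch-effect correction with QC technical replicates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking batch-effect correction with QC technical replicates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(batchsim)
```

## What the package models

Microarray (and, with minor caveats, sequencing) expression studies that
span many hybridization dates acquire per-batch technical shifts. The
package treats a study as a genes × samples log2 matrix whose columns
carry three labels: batch, QC status and subject. QC columns are
technical replicates of a single reference subject, placed in every
batch, so that batch-to-batch drift is directly observable on them.

Three layers make up the benchmark:

1. **Calibration / deconvolution.** From the QC columns we compute per
   gene $i$ and batch $j$ the batch QC mean $q_{ij\cdot}$, the grand QC
   mean $\tau_{i\cdot\cdot}$ (over individual QC measurements, so a
   batch with a single usable QC contributes proportionally), and the
   raw-scale calibration factor $QC_{ij}$, the ratio of the batch's
   arithmetic-mean raw intensity to the all-batch mean. From the
   QC-corrected study samples we compute batch means $\mu_{ij\cdot}$,
   grand means $\mu^*_{i\cdot\cdot}$, the batch-effect SD
   $\gamma = \sqrt{(bw)^{-1}\sum_{ij}(\mu_{ij\cdot}-\mu^*_{i\cdot\cdot})^2}$
   (population form), and per-gene residual SDs $\sigma_{ei}$ as the
   population SD of subject-level residuals about their batch mean.
2. **Simulation.** Known batch effects $r_j \sim N(0,\gamma^2)$, a
   shared per-subject treatment $t \sim N(0,SD^2)$ with unit slope on
   the first $n_{\text{effect}}$ genes, optionally the QC offset term
   $q_{ij\cdot}-\tau_{i\cdot\cdot}$ and per-observation error
   $N(0,\sigma_{ei}^2)$, are added to a base cohort under balanced,
   reduced, batch-size-grid or treatment-sorted unbalanced designs.
3. **Evaluation.** Per-gene p-values from four analyses (OLS, OLS with
   batch fixed effects, random-intercept ML mixed model,
   empirical-Bayes adjustment followed by OLS) are BH-adjusted at 5%
   and scored against the known effect set; ROC AUC, per-PC batch
   association and QC correlations complete the picture.

## The synthetic base cohort

No suitable public cohort ships with the package, so the generator
emulates the structure of a quantile-normalized two-color array study:
251 subjects in 14 batches with two QCs per batch and one
single-QC batch (27 QCs), and per-gene log2 statistics typical of such
data. Defaults, all on the log2 scale:

| parameter | default | rationale |
|---|---|---|
| per-gene baseline mean | $N(7, 2^2)$ | typical location/spread of normalized log2 intensities |
| per-gene residual SD | LogNormal$(\log 0.25, 0.5^2)$ truncated to $[0.05, 1]$ | right-skewed SDs with a realistic bulk near 0.2–0.3 |
| latent batch offset SD | 0.3 | mild technical structure baked into the base data |
| QC technical noise SD | 0.1 | replicate noise well below biological spread |
| batch sizes | 22,21,21,21,17×6,16×4 | sums to 251; the first four batches hold 85 subjects so the reduced design reproduces that sample size |

The marginal distribution of real per-gene SDs is not identifiable from
the emulated study's summary numbers; the truncated log-normal is a
surrogate and every piece of it is exposed in `cohort_config()`.

Two caveats about what the generator does *not* emulate. First,
everything is Gaussian; real expression data have heavier tails,
probe-level artifacts and missingness, so passing tests demonstrate
correctness of the machinery and the relative behavior of the methods,
not their absolute error rates on real data. Second, the generator's QC
columns share the *exact* latent per-(gene, batch) offsets of the study
samples. Real QCs track batches imperfectly, which is precisely why
real studies retain a large batch-effect SD after QC correction. As a
consequence, estimating $\gamma$ on a QC-corrected synthetic cohort
returns a value near zero by construction; the simulator therefore
takes $\gamma$ as a scenario parameter (default 2.72, the scale
estimated from the kind of study the generator emulates) rather than
re-estimating it from synthetic data, and the parameter-recovery test
for $\gamma$ estimates it from batch means computed without the QC
term.

## Design decisions in the statistical layer

**Batch means.** The per-batch mean of QC-corrected values divides by
the per-batch subject count — a true batch mean — rather than the total
subject count. The two coincide only for equal batch sizes; the
batch-mean reading is the one under which the grand mean and the
batch-effect SD have their intended interpretation.

**Residual definition.** $\sigma_{ei}$ measures residuals about batch
means after QC correction, so batch and QC structure are centered out.
This matters because the error arm *adds* these SDs on top of simulated
batch effects: residuals defined about a grand mean would double-count
batch variance.

**Treatment construction.** One per-subject vector $t$ serves both as
the additive shift on effect genes (slope exactly 1) and as the
regression covariate for *every* gene. This is the only construction
under which null genes have a well-defined true slope of zero and
per-gene regression across the whole matrix is meaningful; it also
reproduces the saturation behavior in which a larger treatment SD means
a larger covariate variance and hence more power.

**QC arms.** `with_qc_term = TRUE` injects the per-(gene, batch) QC
offsets into the simulated values (study and QC columns alike — they
travel with their batch, as do the batch effects $r_j$); all four
models are then fit directly to the simulated values. An alternative
reading — re-estimating QC factors on the simulated QCs and calibrating
before analysis — would subtract the simulated $r_j$ itself (the QCs
carry it) and silently remove the batch effect for every method,
including the uncorrected OLS; that arm would no longer measure what QC
calibration contributes, so it is not implemented. Because the offsets
are per-(gene, batch) constants, batch-aware methods absorb them and
the two arms differ by well under 1% in sensitivity, which is the
benchmark's point about the added value of QCs.

**Mixed-model inference.** The random-intercept model is fit by maximum
likelihood, profiling the deviance over the variance ratio
$\lambda = \sigma_u^2/\sigma^2$: for a batch design the inverse and
determinant of $I + \lambda ZZ^\top$ reduce to per-batch closed forms,
so every deviance evaluation costs $O(b)$ after one pass over the data.
This is what makes $10^4$–$10^5$ per-gene fits per study tractable, and
it is exact — the optimum matches `lme4::lmer(REML = FALSE)` and a
dense grid search to numerical precision. The Wald test on $\beta_1$
uses $t_{m-2}$ with the df-corrected residual variance RSS$/(m-2)$, so
that a fit on the $\sigma_u^2 = 0$ boundary reduces *exactly* to
ordinary least squares; reported variance components remain the ML
estimates. Degrees-of-freedom refinements (Satterthwaite and kin) are
out of scope and would only matter at far smaller sample sizes than the
designs studied here.

**Empirical-Bayes adjustment.** The parametric location/scale scheme
standardizes each gene by a batch-size-weighted pooled mean and pooled
variance, estimates per-(gene, batch) location and scale, shrinks them
toward method-of-moments priors (normal for location, inverse-gamma for
scale) by iterating the coupled posterior equations, and
back-transforms. The design matrix contains the batch indicators only:
no covariate is protected, matching a workflow in which correction is a
pre-processing step strictly prior to regression. That choice is also
what makes the method lose sensitivity on treatment-sorted unbalanced
designs — with treatment and batch confounded, removing batch location
removes treatment signal too. The non-parametric prior variant and
reference-batch mode are out of scope.

## Numerical choices

* Profile-ML search: a coarse grid on $\lambda \in \{0\} \cup
  10^{\{-6, -5.5, \dots, 6\}}$ followed by 48 golden-section iterations
  on $\log\lambda$ in the bracketing interval; the zero boundary is
  kept whenever it is no worse than the refined interior optimum.
* EB iteration: relative-change tolerance $10^{-4}$, cap 100
  iterations (both arguments of `eb_batch_adjust()`); genes with zero
  within-batch variance get their scale floored at $10^{-8}$ and are
  flagged rather than dropped.
* BH adjustment: non-finite p-values (failed fits) are excluded from
  the ranking, returned as `NaN`, and counted; the effective test count
  is the number of finite p-values.
* AUC: normalized Mann–Whitney statistic on the p-value ranking, ties
  contributing 1/2, failed fits ranked last.
* PC–batch association: genes centered, not scaled (the data share a
  log2 scale); adjusted $R^2$ of a one-way batch fit per component.
  Under the null its expectation is $-(b-1)/(m-b)$, slightly negative,
  which is the reference level for "batch effect removed".
* Unbalanced design: treatment values are sorted descending across the
  batch blocks (stable sort, so ties keep their order), then a chosen
  fraction of subjects is re-randomized by permuting their values.
* Seeds: a master seed spawns independent per-replicate seeds (all
  below $2^{31}$); every output row records its replicate seed, and
  identical configurations rerun bit-identically.

## Problem sizes used in the shipped checks

The package's own test suite and the reproduction script run the
benchmark at desk scale: 2,000 genes with 500 effect genes, 251
subjects in 14 batches, $\gamma = 2.72$, BH at 5%. Mixed-model cells
use 50 replicates. The comparison of false positives between the
uncorrected and the fixed-effect model uses 400 replicates: uncorrected
false positives arrive in rare replicate-wide bursts (they are driven
by the chance correlation between the treatment draw and the shared
batch draw, which moves every null gene at once), so their mean is
heavy-tailed and needs more averaging than the other summaries. The
full-scale study geometry (27,522 probes, 1,000 replicates) is a
configuration change, not a code change.

## Known limitations

* Gaussian-only generative model; no probe-level preprocessing,
  flagging, quantile normalization or imputation is modelled.
* The mixed model fits a single random intercept per batch; crossed or
  nested technical factors are out of scope.
* The EB adjustment never protects covariates, so its unbalanced-design
  behavior is a property of the benchmarked workflow, not of every
  possible empirical-Bayes variant.
* Mean-only inference differences (e.g. Satterthwaite df, REML) are
  deliberately excluded; at 85+ subjects they are negligible relative
  to the effects studied.
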