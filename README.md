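# batchsim

Simulation benchmarking of batch-effect correction strategies in log2
gene expression data, with and without quality-control (QC)
technical-replicate calibration.

## The problem

Population-scale transcriptome studies hybridize samples in batches, and
each batch leaves a systematic technical imprint on the measured
expression values. Whether to remove that imprint with a per-gene mixed
model, a fixed-effect adjustment, or an empirical-Bayes location/scale
correction — and whether paying for technical replicates of a reference
sample in every batch buys any extra power — is an experimental-design
question that can only be answered on data where the truth is known.
`batchsim` builds that ground truth: it generates multi-batch cohorts
with QC replicates, estimates the calibration and deconvolution
parameters such data imply, injects batch effects and treatment effects
of known size, and scores each correction strategy by true/false
positives under false-discovery-rate control.

## Models

For gene \(i\), subject \(l\) in batch \(j\), the simulator builds

\[ s_{ijl} = x_{ijl} \,[+\, q_{ij\cdot} - \tau_{i\cdot\cdot}] \,+\, r_j
\,+\, t_l\,\mathbf 1\{i \le 500\} \,[+\, e_{ijl}], \]

where \(x\) is the base cohort, \(q_{ij\cdot}\) and
\(\tau_{i\cdot\cdot}\) are the per-batch and grand QC means (the
log-scale QC calibration term), \(r_j \sim N(0, \gamma^2)\) is the batch
effect (\(\gamma = 2.72\) by default), \(t \sim N(0, SD^2)\) is a shared
per-subject treatment variable with unit slope on the first 500 genes,
and \(e_{ijl} \sim N(0, \sigma_{ei}^2)\) is optional residual error with
per-gene SDs estimated from the base cohort. Four per-gene analyses are
fit to each simulated dataset:

* **LM** — ordinary least squares \(y = \beta_0 + \beta_1 t +
  \varepsilon\) (no batch correction);
* **LMBatch** — OLS with batch indicator fixed effects;
* **LMM** — random-intercept model \(y = \beta_0 + \beta_1 t + u_j +
  \varepsilon\), \(u_j \sim N(0, \sigma_u^2)\), maximum likelihood via a
  profiled 1-D search over \(\sigma_u^2/\sigma^2\);
* **LMcom** — parametric empirical-Bayes location/scale batch adjustment
  (ComBat-style) followed by OLS.

P-values are Benjamini–Hochberg adjusted and calls at 5% are scored
against the known effect set (TP/FP, mean adjusted p of calls, ROC AUC).
Diagnostics include per-PC batch association (adjusted R²) before and
after denoising, and pairwise QC correlations.

## Worked example

```r
library(batchsim)

cohort <- generate_base_cohort(cohort_config(n_genes = 2000, seed = 1))
cohort
#> expr_cohort: 2000 genes x 278 samples (251 study, 27 QC) in 14 batches

stats <- calibrate_cohort(cohort)
scen <- simulation_scenario(effect_sd = 0.5, n_replicates = 5, seed = 42)
res <- run_scenario(cohort, stats, scen,
                    methods = c("lmm", "lm", "lm_batch", "eb_lm"))
summarize_replicates(res, 500)$by_method[, c("method", "mean_tp", "mean_fp", "auc")]
#>     method mean_tp mean_fp    auc
#> 1    eb_lm     500    18.8 1.0000
#> 2       lm     200   296.4 0.7992
#> 3 lm_batch     500    19.6 1.0000
#> 4      lmm     500    19.0 1.0000
```

At a moderate effect size (SD 0.5) every batch-aware method recovers all
500 effect genes with false positives near the level the 5% FDR
threshold implies, while the uncorrected model loses three in five true
positives and — whenever the random treatment draw happens to correlate
with the batch draw — rejects null genes in large bursts (here 296 false
positives on average over five replicates). `run_batch_study()` runs
whole scenario grids from a single configuration and writes TSV/JSON
artifacts; `inst/scripts/run_study.R` wraps it for the shell.

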