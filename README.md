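# tmtmark

Biomarker discovery in multi-batch isobaric (TMT) proteomics cohorts.

Cerebrospinal-fluid proteomics studies that compare patient groups — for
example progressive supranuclear palsy (PSP) against Parkinson's disease
(PD) and healthy controls (HC) — quantify thousands of proteins across many
11-plex TMT batches. Each batch carries its own location and scale effects,
so the analysis stands or falls with the experimental design (balanced batch
allocation, a master-pool reference channel, embedded QC aliquots) and the
normalization chain. `tmtmark` implements that full workflow for
statisticians and proteomics analysts, together with a ground-truth
simulator so every stage can be validated without access to raw
mass-spectrometry data.

## What the package computes

**Design and simulation.** `generate_cohort()` draws a three-group clinical
cohort with group-specific age and sex distributions; `block_randomize()`
assigns samples to batches and channels keeping diagnosis, sex and age
balanced (diagnosis balance is guaranteed constructively, sex/age by a
randomized-greedy assignment minimizing an imbalance score), placing the
master pool in the last channel of every batch; `simulate_tmt()` generates
raw reporter abundances

    raw = 2^(baseline + effect * [sample in affected group]
             + batch_shift + noise)

with known per-protein effects (±δ, half up and half down), additive and
multiplicative batch effects, QC channels sharing one latent profile, and a
master pool that measures the mean of the clinical samples' true
abundances.

**Normalization and QC.** `mp_normalize()` forms log2(sample/master-pool)
ratios, which cancels additive per-batch shifts exactly;
`filter_complete()` applies the complete-case protein filter;
`combat_correct()` removes residual batch location/scale effects with the
parametric empirical-Bayes ComBat adjustment; `compute_qc_metrics()`
reports the per-protein coefficient of variation of the QC channels
(CV = SD/mean on the un-logged scale) and the signal-to-noise ratio
S/N = SD(clinical)/SD(QC); `pca_batch_diagnostic()` exposes batch structure
on principal components.

**Differential abundance.** The core statistic is a per-protein bootstrap
ROC: the Mann–Whitney AUC (ties count one half) recomputed over 500
stratified resamples gives a mean and SD per protein; one global label
permutation yields a null AUC distribution, and a threshold walk converts
the two into permutation q-values

    q(t) = monotonized  #(permuted AUC at least as extreme as t)
                      / #(observed AUC at least as extreme as t)

walked separately above and below AUC = 0.5. `run_differential()` calls a
protein `up`/`down` when q < 0.01.

**Classification, enrichment, power.** `plsda_fit()` (NIPALS PLS-DA, two
latent variables), `vip_scores()` (variable importance in projection,
Σ VIP² = number of features), and `mccv_evaluate()` (balanced 2/3–1/3
Monte-Carlo cross-validation, 50 iterations, VIP feature ranking, accuracy
and pooled ROC per panel size) reproduce the multivariate marker-panel
analysis; `fisher_enrichment()` tests cell-type marker sets by one-sided
Fisher exact tests; `t_test_power()` / `min_sample_size()` perform the
noncentral-t power planning behind the cohort size.

## Worked example

```r
library(tmtmark)

design <- block_randomize(generate_cohort(n_per_group = 40, seed = 1),
                          n_batches = 13, channels = tmt11_channels(),
                          n_qc_batches = 10, seed = 1)
sim <- simulate_tmt(design, n_proteins = 500, frac_differential = 0.17,
                    missing_rate = 0, seed = 2)
corrected <- combat_correct(
  filter_complete(mp_normalize(sim$matrix, design)), design)
corrected
#> abundance_matrix: 500 proteins x 130 samples [log2_corrected]

qc <- compute_qc_metrics(corrected, design)
sprintf("median CV %.3f; %.1f%% of proteins with S/N >= 1",
        median(qc$cv, na.rm = TRUE), 100 * mean(qc$snr >= 1, na.rm = TRUE))
#> "median CV 0.073; 100.0% of proteins with S/N >= 1"

de <- run_differential(corrected, design, positive = "PSP",
                       comparator = c("PD", "HC"), seed = 3)
de
#> Bootstrap-ROC differential abundance: PSP vs PD+HC
#>   500 proteins, 500 bootstrap resamples, q cutoff 0.01
#>   calls: 44 up, 42 down
#>   protein_id   auc_mean     auc_sd q_value direction
#> 1      P0342 0.07630250 0.02479254       0      down
#> 2      P0192 0.92339875 0.02301997       0        up
#> ...
```

The simulation planted 85 differential proteins (17% of 500 at
|δ| = log2(1.35) with σ = 0.338); 86 are called at q < 0.01, split into 44
up- and 42 down-regulated, with the strongest calls reaching bootstrap mean
AUCs above 0.92 (or below 0.08 for down-regulated proteins).

Power planning for that effect size:

```r
min_sample_size(delta = 0.433, sigma = 0.338, alpha = 1e-4,
                power_target = 0.8)
#> [1] 31
#> attr(,"n_exact")  31.08336
#> attr(,"power")    0.7979755
```

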