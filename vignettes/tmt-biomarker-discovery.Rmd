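---
title: "Multi-batch TMT biomarker discovery: models and methods"
author: "tmtmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-batch TMT biomarker discovery: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmtmark)
```

# The problem

Isobaric (TMT) labelling quantifies up to 11 samples per mass-spectrometry
run through reporter-ion intensities. A 120-sample case–control cohort —
here three diagnosis groups of 40: progressive supranuclear palsy (PSP),
Parkinson's disease (PD) and healthy controls (HC) — therefore spans 13
batches, and everything downstream is dominated by two design devices:

* a **master pool (MP)**, an equal-volume mix of all clinical samples,
  measured in the last channel of every batch as a common denominator;
* **QC channels**, identical aliquots of one control sample embedded in 10
  of the 13 batches to expose purely technical variation.

`tmtmark` implements the batch design, a generative model of such data, the
normalization chain, the bootstrap-ROC differential-abundance statistic,
PLS-DA marker-panel classification, marker-set enrichment and the power
planning, with every stage testable against simulated ground truth.

# The generative model

For protein $p$ in sample $s$ of batch $b$,

$$\mathrm{raw}_{ps} = 2^{\,\mu_p + \delta_p\,[s \in \text{affected group}]
  + \gamma_{pb} + \varepsilon_{ps}},\qquad
  \varepsilon_{ps} \sim N(0, (\sigma\,\lambda_b)^2),$$

with baseline $\mu_p \sim N(6, 2^2)$ (log2 units; the location is
arbitrary and cancels in the MP ratio), additive batch shifts
$\gamma_{pb} \sim N(0, \tau^2)$, and per-batch multiplicative noise
inflation $\lambda_b = e^{N(0,\,0.1^2)}$. A fraction of proteins carries a
signed effect $\delta_p = \pm\delta$ in the affected group, half up and
half down. The MP channel measures the mean of the clinical samples' true
(noise-free) abundances on the linear scale; QC channels share one latent
profile $\mu_p + N(0, \sigma^2)$ drawn once per protein. MP and QC
measurements carry technical noise only. Missing values are completely at
random in clinical and QC channels, never in the MP.

Default parameter choices and their rationale:

| parameter | default | units | why |
|---|---|---|---|
| `sigma` | 0.338 | log2 | residual SD of CSF protein ratios typical of in-house TMT experiments; also the value used in the power planning |
| `delta` | log2(1.35) = 0.433 | log2 | the smallest fold change the design aims to detect |
| `frac_differential` | 0.17 | – | the analyzed-cohort scale (≈247 of 1409 proteins differential); the true fraction is unknowable, so this is a free parameter |
| `batch_shift_sd` | 0.5 | log2 | makes the batch effect clearly dominant before correction (batch variance fraction ≈ 40–60%), the regime batch correction exists for |
| `batch_scale_sd` | 0.1 | log of factor | mild scale heterogeneity (±10% noise SD per batch) |
| `qc_noise_sd` | 0.1 | log2 | technical-only noise; yields QC CVs around 7% and S/N ≈ 2–4, matching a high-quality TMT experiment in which >95% of proteins show S/N ≥ 1 |
| `missing_rate` | 0.008 | – | per-cell dropout giving roughly the observed complete-case attrition (about 40% of proteins observed in all 120 samples) |

Cohort demographics default to `default_demographics()`: group mean ages
68.8 / 64.1 / 67.7 years (SD 7.1, floored at 18) and female proportions
0.60 / 0.475 / 0.675, i.e. 70 of 120 samples female. The age SD comes from
inverting a 95% CI half-width of ≈2.2 years at $n = 40$.

**What the simulator does not emulate.** No peptide-to-protein rollup, no
reporter-ion ratio compression or isotope impurity, no
intensity-dependent missingness, no correlation between proteins beyond
batch effects, and lognormal abundances by construction. Tests passing on
these simulations therefore validate the statistical machinery — balance,
normalization algebra, error control, ranking — not the mass-spectrometric
error structure of real data.

# Batch design

`block_randomize()` first fixes per-batch clinical counts by water-filling
against channel capacity (the MP always occupies the last channel; QC
batches lose one more slot), then allocates each diagnosis group across
batches by largest-remainder rounding of the proportional ideal — this
makes the per-batch group-count deviation < 1 by construction. Individuals
are then placed into those slots by a randomized greedy pass minimizing

$$\sum_b (F_b - n_b\,p_F)^2 +
  \sum_b \left(\frac{\bar a_b - \bar a}{\mathrm{sd}(a)}\right)^2$$

($F_b$ female count, $\bar a_b$ mean age in batch $b$), refined by
accept-if-better pairwise swaps within a diagnosis group (400 attempts),
with 50 restarts keeping the best score. Any assignment satisfying the
balance invariants is acceptable; this scheme also keeps per-batch sex
counts within one of proportional allocation in practice.

# Normalization chain

1. **MP ratio** (`mp_normalize`): $\log_2(\mathrm{raw}_{ps} /
   \mathrm{raw}_{p,\mathrm{MP}(b)})$. Because the MP is measured in every
   batch, the additive shift $\gamma_{pb}$ cancels exactly; a missing or
   non-positive MP value invalidates that protein's batch (set missing,
   with a warning).
2. **Complete-case filter** (`filter_complete`): proteins with any missing
   value are dropped; no imputation anywhere in the pipeline.
3. **Empirical-Bayes batch correction** (`combat_correct`): the parametric
   ComBat location/scale adjustment (via the `sva` package) on the
   complete log2-ratio matrix, with no covariates — block randomization is
   what protects group signal from being absorbed, and the function emits a
   note when groups are visibly unbalanced across batches. Zero-variance
   proteins are left unchanged (warning); a single-batch matrix is returned
   unchanged, there being nothing to correct. Because the EB step shrinks
   per-batch estimates toward their priors, correction is exact only when
   every protein carries the same standardized batch effect; in general a
   small residual batch-mean component remains (a few percent of proteins
   can retain an across-batch variance fraction slightly above 5% even
   when the typical protein is far below it).

QC metrics use the sample SD ($n-1$) throughout; the CV is computed on
un-logged MP-ratio values, as the ratio scale is what the pipeline
quantifies. A zero QC SD yields `cv = 0` and an `Inf` S/N sentinel,
excluded from summaries.

# Bootstrap-ROC differential abundance

For each protein the Mann–Whitney AUC (ties one half, computed from
midranks) is bootstrapped with 500 stratified resamples — each class
resampled with replacement to its own size, which preserves class balance
and cannot produce empty classes. `run_differential()` shares one set of
resample draws across proteins within a comparison: the resampling acts on
samples, not proteins, so this preserves the inter-protein correlation
structure exactly as the single global label permutation does. The
permuted labels (one permutation by default; more can be averaged via
`n_perm`) give a null AUC vector, and q-values come from a two-branch
threshold walk: above 0.5 with descending thresholds, below 0.5 ascending,
FDR(t) = #(permuted at least as extreme)/#(observed at least as extreme),
clipped to [0, 1] and monotonized by a running minimum toward less extreme
thresholds (so q never decreases with rank; an AUC of exactly 0.5 gets
q = 1). Thresholds sit at the observed values with inclusive comparisons.

The ratio direction deserves a note: a verbal description of this
procedure can be read as observed/permuted, but only permuted/observed
yields a false-discovery-rate estimate in [0, 1] consistent with calling
proteins at q < 0.01, so that is what is implemented.

Calibration and recovery at the study scale (1409 proteins, 40 vs 80,
σ = 0.338) are part of the test suite: null simulations yield well under
1% of proteins called at q < 0.01, and with 10% of proteins at
|δ| = 0.433 the median sensitivity exceeds 0.6 at an empirical FDR ≤ 0.05.

# PLS-DA, VIP and Monte-Carlo cross-validation

`plsda_fit()` is NIPALS PLS1 on column-standardized features against the
centered 0/1 response: unit-norm weight vectors maximizing covariance with
the response, X-deflation between components, two latent variables by
default. Class prediction thresholds the continuous score at the midpoint
of the training class means — the upstream convention is undocumented, and
the midpoint is the natural symmetric choice. VIP scores use
$\mathrm{VIP}_j = \sqrt{p \sum_a SS_a w_{ja}^2 / \sum_a SS_a}$ and satisfy
$\sum_j \mathrm{VIP}_j^2 = p$ exactly (asserted after every fit in the
tests).

`mccv_evaluate()` runs 50 stratified 2/3–1/3 splits ("balanced" meaning
class proportions preserved in both thirds, the sensible reading with a
40-vs-80 comparison). Each iteration ranks features by the VIP of a
full-feature fit (ties broken by feature identifier for reproducibility)
and refits each requested top-$k$ panel. Accuracy is averaged over
iterations; validation scores are pooled into one ROC per $k$ with a
2.5/97.5 percentile interval of per-iteration AUCs; `best_k` is the
smallest $k$ attaining the maximal accuracy. Average importance defaults
to the mean VIP over all iterations (a feature absent from a panel still
has a ranking-fit VIP); `importance_over = "selected"` averages only over
iterations where the feature entered the top panel. All stochastic steps
consume one master seed in a fixed draw order.

With exactly five informative features among noise, accuracy peaks at
$k = 5$ and declines toward $k = 53$ — the overfitting signature the
panel-size sweep is designed to expose.

# Enrichment and power

`fisher_enrichment()` computes the one-sided hypergeometric upper tail
$P(X \ge \text{overlap})$ per marker set (identical to the one-sided
Fisher exact test; both routes are compared to 1e-10 in the tests), after
case-insensitive identifier collapsing and intersection of each set with
the background. The background should be the quantified-protein universe
of the analyzed matrix, not the full identification list. P-values are
reported raw — no multiplicity correction across cell types.

`t_test_power()` is the exact two-sided two-sample noncentral-t power
(noncentrality $d\sqrt{n/2}$, $2n-2$ df, both rejection tails).
`min_sample_size()` solves the *continuous* sample-size equation — exactly
what standard calculators report — and returns the nearest integer, with
the continuous root and the achieved integer-n power as attributes. At
δ = 0.433, σ = 0.338, α = 1e-4, power 0.8 the root is 31.08, reported as
31; the exact power at the integer 31 is 0.798, a reminder that the
reported design size sits a rounding step below the nominal target. At
α = 0.05 the same effect size gives 11 per group.

# Numerical and testing choices

* Bootstrap AUCs for whole matrices run through a small C++ kernel
  (midrank ties, contiguous per-protein memory); the scalar R
  implementation is the cross-checked reference.
* Exhaustive resample enumeration (all stratified bootstrap draws at
  n ≤ 6) anchors the Monte-Carlo bootstrap; pair enumeration anchors the
  AUC; a double-loop walk anchors the q-values; `fisher.test`,
  `power.t.test` (strict two-sided), `wilcox.test` and `mixOmics::plsda`
  serve as independent implementations where one exists.
* Test problem sizes: full 13×11 design for calibration/recovery (1409
  proteins, 10 simulation seeds each), 4×11 designs (36 clinical samples,
  200–400 proteins) for distributional properties, toy fixtures for exact
  algebra. The KS comparison of QC and clinical CV distributions uses
  simulations whose clinical dispersion equals the QC technical noise and
  matches the number of observations per CV estimate — otherwise sample
  size alone separates the distributions.

# Limitations

* Complete-case filtering discards information and, under
  intensity-dependent missingness in real data, can bias the retained set;
  the simulator's MCAR dropout does not probe that.
* One label permutation gives a noisy null for very small matrices; use
  `n_perm > 1` there.
* ComBat without covariates assumes the randomization succeeded; with
  strongly unbalanced designs the group signal can be attenuated.
* PLS-DA panels are ranked by VIP only; no nested tuning of the component
  count, and no classifier beyond PLS-DA.
* Enrichment p-values depend on the chosen background; published
  cell-type tables are generally not recomputable without the original
  marker sets and background.
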