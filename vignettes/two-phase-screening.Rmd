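---
title: "Two-phase screening and testing of expression features for survival"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-phase screening and testing of expression features for survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survscreen)
```

## The problem

Prognostic studies of bulk gene expression face a dimension problem: tens of
thousands of features, a few hundred right-censored outcomes, and clinical
covariates (age, stage, smoking history, histology) that must be adjusted
for throughout. `survscreen` implements a two-phase *screen, then test*
design for this setting:

1. **Screening.** A random survival forest ranks features by permutation
   importance while every clinical covariate is kept available as a split
   candidate at every node of every tree, so no tree is ever grown
   unadjusted. Features are then added one at a time in importance order;
   the out-of-bag (OOB) error of each nested model traces a curve whose
   smoothed minimum fixes the candidate set (sliding-window sequential
   forward selection, SWSFS).
2. **Testing.** Each candidate gene is tested for a main effect with a
   covariate-adjusted Cox model,
   $h(t) = h_0(t)\exp(\alpha_1 x_g + \sum_i \beta_i z_i)$, and every
   unordered candidate pair for an interaction,
   $h(t) = h_0(t)\exp(\alpha_1 x_{g_1} + \alpha_2 x_{g_2} +
   \alpha_3 x_{g_1} x_{g_2} + \sum_i \beta_i z_i)$, with Benjamini–Hochberg
   FDR control within each scan. A sensitivity branch repeats the scans on
   TMM-normalized counts; only terms simultaneously significant in both
   normalizations (with agreeing effect directions) survive.
3. **Validation.** Survivors are re-tested on an independent cohort
   measured on a different platform. A discovery gene absent from that
   platform is replaced by its *surrogate*: the platform-shared gene with
   maximal, FDR-significant correlation in the discovery data. A term is
   confirmed when its focal coefficient is nominally significant
   (p ≤ 0.05) in validation *and* its direction agrees across phases.
4. **Model comparison.** The prognostic value of the confirmed genes is
   quantified by comparing a covariates-only Cox model against one with
   the expression terms added, using time-dependent ROC/AUC at 3- and
   5-year horizons (cumulative cases / dynamic controls, Kaplan–Meier
   censoring correction) with subject-level bootstrap confidence intervals
   for the AUC difference.

The package ships a synthetic-data generator with known ground truth so
that every stage — and the pipeline end to end — can be evaluated for type-I
error and recovery power.

## What the generator emulates, and what it does not

`sim_config()` describes a cohort whose statistical skeleton matches a
two-platform expression–survival study:

* **Expression.** Latent per-gene values are Gaussian on the log2 scale,
  drawn in blocks with compound-symmetric correlation (default 0.9 within
  blocks of 2), so every gene has a natural surrogate on a partially
  overlapping platform. The FPKM-like matrix is the exponentiated latent
  (log-normal, positive); the count matrix is Poisson with log-normal
  library sizes around 2×10⁵ reads, so the TMM branch has real
  between-library variation to correct.
* **Clinical covariates.** Age ~ N(66.02, 9.55²); pack-years
  ~ N(47.38, 29.96²) truncated at zero; sex, race, smoking status, stage
  I–IV and LUAD/LUSC histology drawn with the discovery-cohort frequencies
  of a large non-small-cell lung cancer series (stage 54.3/28.3/14.6/2.8%,
  etc.). These defaults are configurable.
* **Survival.** A Weibull proportional-hazards model (default shape 1.2,
  scale 8 years) with linear predictor built from per-SD gene effects,
  the product term for the configured interacting pair, and covariate
  effects (the stage trend dominating, as in real cohorts). Censoring
  times are uniform with their scale calibrated by root finding so the
  realized censoring rate hits the target (default 59.6%, checked to
  ±0.03 at n = 5000).
* **Two platforms.** The validation cohort is generated independently with
  its own sub-seed, then restricted to `floor(overlap × n_genes)` genes;
  with `force_missing = TRUE` every truth gene is dropped from the
  validation platform while a block partner is kept, so the surrogate path
  is genuinely exercised.

It does **not** emulate batch effects, probe-level artifacts, gene-length
biases, heavy-tailed count dispersion, or non-proportional hazards. A
green pipeline on this generator therefore demonstrates correctness of the
statistical machinery and its operating characteristics under a clean
proportional-hazards world, not robustness to the messiness of consortium
data.

Hazard coefficients for genes are **per standard deviation of the log2
expression scale** (the generator standardizes internally); real studies
rarely state the scale of reported hazard ratios, and per-SD coding makes
effect sizes comparable across genes.

One placement rule matters: planted effects default to *different*
correlation blocks. Two opposite-signed effects inside one ρ = 0.9 block
largely cancel in the hazard — a configuration no study would describe as
"three informative genes" — and early development runs confirmed the
cancellation.

## Tunable parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `n_trees` | 1000 | forest size; importance stability grows with it |
| `mtry` | `sqrt` | genes sampled per split (covariates ride along for free when forced) |
| `min_node_size` | 15 | terminal node size; larger = shallower, faster, smoother trees |
| `swsfs_window` | 5 | centered moving-average width on the OOB curve |
| `k_max` | 50 | largest candidate set SWSFS examines |
| `q_threshold_discovery` | 0.05 | BH-FDR level per scan and for the sensitivity intersection |
| `p_threshold_validation` | 0.05 | nominal level for confirmation |
| `horizons` | 3, 5 years | time-dependent AUC horizons |
| `n_boot` | 1000 | bootstrap replicates for the AUC comparison |

## Numerical and design choices

* **OOB error for survival** is 1 − Harrell's C between the OOB ensemble
  mortality (cumulative hazard summed over a sample's out-of-bag trees)
  and the observed outcomes, tied predictions counting one half. This is
  the standard survival-forest convention; the implementation is verified
  against exhaustive pair enumeration.
* **The 100%-covariate rule** is structural, not probabilistic: covariates
  are passed to the forest as always-available split candidates, which
  makes the contract auditable (every node considers every covariate)
  instead of approximated by sampling weights.
* **SWSFS smoothing** truncates the window at the curve's boundaries and
  breaks argmin ties toward the smallest k (parsimony).
* **Cox fitting** uses Efron tie handling; Wald 95% CIs use the 1.96
  normal quantile. Constant or rank-deficient designs are rejected before
  fitting; diverging coefficients (monotone likelihood) are reported.
  FDR families are kept separate for the main-effect scan (k tests) and
  the interaction scan (k(k−1)/2 tests); pooling is not done because the
  two scans answer different questions at very different scales.
* **Direction agreement** in the sensitivity intersection and in
  validation applies to the focal term only (α₁ or α₃). Constituent main
  terms of an interaction may flip between platforms without invalidating
  the interaction; requiring constituent consistency would reject
  genuinely validated interactions.
* **Surrogate correlations** are computed in the discovery data (the only
  place target and candidate are jointly observed), Pearson on the
  modeling scale by default, with BH-FDR per target and |r| ties broken
  by gene id.
* **Time-dependent ROC** uses the cumulative-case/dynamic-control
  Kaplan–Meier estimator, vectorized over score-ordered prefixes; on
  uncensored data it reduces exactly to the empirical ROC with tied
  scores scoring one half. Bootstrap model comparison *refits* both
  models in every replicate, so selection optimism is reflected in the
  interval rather than hidden.
* **Dichotomization** sends ties to the low group; the cut is always
  recorded in the output.
* **Determinism.** Every stochastic stage derives its seed from the
  master seed plus a stage counter (`derive_seed`), so stages can be
  re-run in isolation and reproduce the full-pipeline artifact bit for
  bit.
* **TMM** delegates to the reference implementation of the published
  method (trims 0.30/0.05, precision weighting, geometric-mean-1
  rescaling), with the reference library chosen by the upper quartile of
  nonzero relative abundances, ties to the smallest sample id. Exact
  scale invariance holds for the M values; the precision weights see
  absolute counts, so scaling one library moves factors only in the third
  decimal.

## Problem sizes used in the shipped experiments

The analysis scripts and the test suite run the pipeline at desk scale,
chosen once as a realistic miniature of the design: discovery n = 700,
validation n = 500, 40 genes in blocks of 2, three planted main effects
(per-SD |log HR| = 0.6), one planted interacting pair (interaction log HR
0.7 with constituent effects ∓0.35, mirroring the situation where both
pair members also carry main effects), ~60% censoring, a 150-tree ranking forest with 120-tree SWSFS refits
(`min_node_size` 30, `k_max` 20, smoothing window 7 — the error curve is
smoothed across k, so the per-k refits tolerate fewer trees than the
importance fit, and the wider window stabilizes the argmin under the
extra refit noise), and 200–1000 bootstrap replicates depending on the
script. Null (all-zero) versions of
the same configurations back the type-I-error checks. Operating
characteristics (recovery in ≥ 8/10 seeded replicates, null pass rates
below the nominal level) are recomputed, not asserted from memory, by the
test suite and `scripts/acceptance.R`.

## Known limitations

* Screening power for *pure* interactions (no marginal effect on either
  gene) is weak — marginal importance is what a forest measures. The
  shipped study conditions give the pair constituent effects, as observed
  in the motivating class of studies.
* The bootstrap AUC comparison refits models but does not re-run
  screening or FDR selection inside replicates; the interval reflects
  coefficient and sampling noise, not selection-path uncertainty.
* `p = 0` from `cor.test` at machine precision is clamped to the smallest
  positive double before FDR adjustment.
* The generator's Poisson counts are underdispersed relative to real
  RNA-seq; TMM factors are correspondingly mild. The TMM implementation
  itself is tested against an independent hand-coded oracle on inflated
  fixtures.
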