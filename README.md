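# survscreen

Two-phase screening and testing of expression features for right-censored
survival, with trans-platform surrogate validation.

## The problem

Given a genes × samples expression matrix, clinical covariates and
right-censored survival, which features carry prognostic signal — alone or
through gene–gene interactions — after covariate adjustment, and does that
signal replicate on an independent cohort measured on a different platform
that may not even contain the same genes?

`survscreen` implements the full workflow:

* **Screening** — a random survival forest in which every clinical
  covariate is a split candidate at every node (so no tree is unadjusted)
  ranks genes by permutation importance; sliding-window sequential forward
  selection (SWSFS) picks the candidate set at the minimum of the smoothed
  out-of-bag error curve.
* **Testing** — covariate-adjusted Cox proportional-hazards scans of every
  candidate, `h(t) = h0(t)·exp(α₁·gene + Σ βᵢ·covᵢ)`, and of every
  unordered candidate pair,
  `h(t) = h0(t)·exp(α₁·g₁ + α₂·g₂ + α₃·g₁g₂ + Σ βᵢ·covᵢ)`, with
  Benjamini–Hochberg FDR per scan; a TMM-normalized count branch serves as
  a sensitivity analysis, and only terms significant in **both**
  normalizations (same direction) go forward.
* **Validation** — discovery genes absent from the validation platform are
  replaced by surrogates (maximal FDR-significant correlation in the
  discovery data); a term is confirmed when its focal term has p ≤ 0.05 on
  the validation cohort with a consistent direction. Histology-stratified
  refits and median-split Kaplan–Meier analyses characterize confirmed
  hits.
* **Model comparison** — covariates-only vs covariates-plus-genes Cox risk
  scores compared by time-dependent AUC (cumulative cases / dynamic
  controls, Kaplan–Meier censoring correction) at 3- and 5-year horizons,
  with subject-level bootstrap CIs and p-values for the AUC gain.
* **Synthetic data** — a generator with known ground truth (block-correlated
  log-normal expression on two partially overlapping platforms, Weibull
  survival with calibrated censoring, realistic clinical marginals) so the
  pipeline's type-I error and recovery power are measurable.

## Worked example

```r
library(survscreen)

cfg <- sim_config(n_subjects = 700, n_genes = 40,
                  n_informative_main = 3, informative_idx = c(1L, 3L, 5L),
                  main_log_hr = c(0.6, -0.6, 0.6),
                  interaction_pair = c(21L, 25L), interaction_log_hr = 0.7,
                  interaction_main_log_hrs = c(-0.35, 0.35),
                  platform_overlap_fraction = 0.85,
                  surrogate_correlation = 0.9, seed = 1L)
tp <- simulate_two_phase(cfg, n_validation = 500, force_missing = TRUE)

pcfg <- pipeline_config(
  forest = forest_config(n_trees = 150, min_node_size = 30, seed = 1L),
  swsfs_forest = forest_config(n_trees = 120, min_node_size = 30, seed = 1L),
  swsfs_window = 7, k_max = 20, n_boot = 200, seed = 1L)
disc <- run_discovery(tp$discovery$fpkm, tp$discovery$counts,
                      tp$discovery$clinical, tp$discovery$survival, pcfg)
disc$selected_k
#> [1] 13
disc$interaction_retained$term
#> [1] "GENE0021:GENE0025" "GENE0021:GENE0026" "GENE0022:GENE0025"
#> [4] "GENE0022:GENE0026"

val <- run_validation(disc, tp$validation$fpkm,
                      tp$validation$clinical, tp$validation$survival)
subset(val$verdicts,
       passed & term %in% c("GENE0001", "GENE0003", "GENE0005",
                            "GENE0021:GENE0025"),
       c(analysis, term, surrogates, validation_hr, validation_p))
#>       analysis              term        surrogates validation_hr validation_p
#> 1         main          GENE0005          GENE0006         1.549     3.86e-07
#> 2         main          GENE0003          GENE0004         0.597     1.25e-07
#> 3         main          GENE0001          GENE0002         2.075     1.60e-11
#> 12 interaction GENE0021:GENE0025 GENE0022:GENE0026         1.368     4.34e-03

val$auc$horizon_3[c("auc_basic", "auc_optimized", "delta", "ci", "p")]
#> $auc_basic
#> [1] 0.676
#> $auc_optimized
#> [1] 0.843
#> $delta
#> [1] 0.167
#> $ci
#> [1] 0.107 0.211
#> $p
#> [1] 0.00995
```

The three planted main-effect genes and the planted interacting pair were
forced off the validation platform; each validates through its correlated
(r ≈ 0.9) block partner — `GENE0002`, `GENE0004`, `GENE0006`, and the pair
partners `GENE0022`/`GENE0026` — with hazard-ratio directions matching the
planted signs (+0.6, −0.6, +0.6 per SD, interaction +0.7). Because block
partners are nearly interchangeable with their planted genes, the
candidate set and retained terms also include partner echoes
(`GENE0021:GENE0026` and the like); the validation table reports each. The
3-year AUC comparison shows the expression terms lifting a covariates-only
model from 0.68 to 0.84 with a bootstrap CI excluding zero.

The same workflow, at the same sizes, is scripted as a narrative analysis
under `analysis/` (run `01_simulate.R` … `04_effect_modification.R` from
the repository root; tables land under `results/`).

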