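#!/usr/bin/env Rscript
# Generate the synthetic two-phase study used by the downstream analysis
# scripts: a discovery cohort with three planted main-effect genes and one
# planted interacting pair, and an independent validation cohort measured on
# a partially overlapping platform with the truth genes deliberately absent
# (so validation must go through surrogates). Writes the dataset directory
# under results/data/.

library(survscreen)

seed <- 1L
out <- file.path("results", "data")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(
  n_subjects = 700, n_genes = 40,
  n_informative_main = 3, informative_idx = c(1L, 3L, 5L),
  main_log_hr = c(0.6, -0.6, 0.6),
  interaction_pair = c(21L, 25L), interaction_log_hr = 0.7,
  interaction_main_log_hrs = c(-0.35, 0.35),
  platform_overlap_fraction = 0.85, surrogate_correlation = 0.9,
  target_censoring_rate = 0.596,
  seed = seed)

tp <- simulate_two_phase(cfg, n_validation = 500, force_missing = TRUE)

for (phase in c("discovery", "validation")) {
  coh <- tp[[phase]]
  write_expression(coh$fpkm, file.path(out, paste0(phase, "_fpkm.tsv")))
  write_expression(coh$counts, file.path(out, paste0(phase, "_counts.tsv")))
  write.csv(coh$clinical, file.path(out, paste0(phase, "_clinical.csv")),
            row.names = FALSE)
  write.csv(coh$survival, file.path(out, paste0(phase, "_survival.csv")),
            row.names = FALSE)
}
jsonlite::write_json(tp$truth, file.path(out, "truth.json"), auto_unbox = TRUE,
                     digits = NA)

cat(sprintf("discovery: %d genes x %d samples, censoring %.1f%%\n",
            nrow(tp$discovery$fpkm), ncol(tp$discovery$fpkm),
            100 * mean(tp$discovery$survival$event == 0)))
cat(sprintf("validation: %d genes x %d samples, censoring %.1f%%\n",
            nrow(tp$validation$fpkm), ncol(tp$validation$fpkm),
            100 * mean(tp$validation$survival$event == 0)))
cat("truth genes:", paste(c(tp$truth$informative_gene_ids,
                            tp$truth$interaction_pair_ids), collapse = ", "), "\n")
cat("on validation platform:",
    paste(intersect(c(tp$truth$informative_gene_ids, tp$truth$interaction_pair_ids),
                    rownames(tp$validation$fpkm)), collapse = ", "), "(none expected)\n")
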