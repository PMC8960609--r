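test_that("concordance error matches hand enumeration and tie conventions", {
  # 4 subjects, all events: 6 comparable pairs, one discordant
  time <- c(1, 2, 3, 4); event <- rep(1, 4)
  score <- c(4, 3, 1, 2)   # the (3,4) pair is discordant
  expect_equal(concordance_error(score, time, event), 1 / 6)
  expect_equal(concordance_error(rep(1, 4), time, event), 0.5)
  expect_equal(concordance_error(c(4, 3, 2, 1), time, event), 0)

  set.seed(5)
  for (i in 1:10) {
    n <- sample(10:50, 1)
    time <- round(rexp(n), 2)
    event <- rbinom(n, 1, 0.7)
    score <- sample(5, n, replace = TRUE)  # force prediction ties
    if (sum(event) == 0) next
    expect_equal(concordance_error(score, time, event),
                 oracle_concordance_error(score, time, event))
  }
})

test_that("forest fits are deterministic and record OOB machinery", {
  pc <- planted_cohort(41, n = 150, n_genes = 8)
  fc <- forest_config(n_trees = 60, seed = 5)
  f1 <- fit_survival_forest(pc$x, pc$covars, pc$outcome, fc)
  f2 <- fit_survival_forest(pc$x, pc$covars, pc$outcome, fc)
  expect_identical(f1$oob_mortality, f2$oob_mortality)
  expect_identical(oob_error(f1), oob_error(f2))
  expect_identical(variable_importance(f1), variable_importance(f2))
  # OOB error equals brute-force all-pairs concordance on the OOB mortality
  pc_small <- planted_cohort(42, n = 50, n_genes = 6)
  fs <- fit_survival_forest(pc_small$x, pc_small$covars, pc_small$outcome,
                            forest_config(n_trees = 80, seed = 2))
  expect_equal(oob_error(fs),
               oracle_concordance_error(fs$oob_mortality,
                                        pc_small$outcome$time,
                                        pc_small$outcome$event))
})

test_that("forcing covariates makes them available at every split", {
  # one strongly prognostic covariate among pure-noise genes, mtry = 1:
  # with forcing the forest must use it, without forcing it rarely can
  set.seed(9)
  n <- 250
  stage <- rbinom(n, 1, 0.5)
  time <- rexp(n, exp(2.5 * stage)); event <- rep(1, n)
  genes <- matrix(rnorm(n * 30), n, 30,
                  dimnames = list(NULL, sprintf("G%02d", 1:30)))
  outc <- data.frame(time = time, event = event)
  covars <- data.frame(stage = stage)
  forced <- fit_survival_forest(genes, covars, outc,
                                forest_config(n_trees = 80, mtry = 1,
                                              covariates_forced = TRUE, seed = 3),
                                importance = FALSE)
  unforced <- fit_survival_forest(genes, covars, outc,
                                  forest_config(n_trees = 80, mtry = 1,
                                                covariates_forced = FALSE, seed = 3),
                                  importance = FALSE)
  expect_lt(oob_error(forced), oob_error(unforced) - 0.02)
  expect_identical(forced$covariate_names, "stage")
  expect_true(forced$config$covariates_forced)
  expect_false(unforced$config$covariates_forced)
})

test_that("permutation importance separates planted signal from noise", {
  hits <- 0
  for (seed in 1:5) {
    pc <- planted_cohort(seed, n = 300, n_genes = 30, main = 1, idx = 7L)
    f <- fit_survival_forest(pc$x, pc$covars, pc$outcome,
                             forest_config(n_trees = 150, seed = seed))
    rk <- variable_importance(f)
    if (rk$gene_id[1] == "GENE0007") hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("noise-gene importance concentrates around zero", {
  imps <- sapply(1:6, function(seed) {
    pc <- planted_cohort(seed + 100, n = 250, n_genes = 10, main = 0,
                         idx = integer(0))
    f <- fit_survival_forest(pc$x, pc$covars, pc$outcome,
                             forest_config(n_trees = 120, seed = seed))
    variable_importance(f)$importance
  })
  m <- mean(imps); se <- sd(imps) / sqrt(length(imps))
  expect_lt(abs(m), 2 * se + 0.005)
})

test_that("sliding-window smoothing and k selection follow the windowed-argmin rule", {
  # V-shaped curve with window 1: vertex selected
  v <- c(0.5, 0.4, 0.3, 0.35, 0.45)
  expect_equal(select_k_min_oob(v, window = 1)$selected_k, 3L)

  raw <- c(0.40, 0.30, 0.31, 0.30, 0.45)
  sel <- select_k_min_oob(raw, window = 3)
  expect_equal(sel$smoothed,
               c(0.35, mean(c(.40, .30, .31)), mean(c(.30, .31, .30)),
                 mean(c(.31, .30, .45)), 0.375),
               tolerance = 1e-12)
  expect_equal(sel$selected_k, 3L)
  # ties resolve to the smallest k
  expect_equal(select_k_min_oob(c(0.3, 0.3, 0.4), window = 1)$selected_k, 1L)
  expect_error(sliding_window_smooth(v, window = 2), "window")
})

test_that("SWSFS recovers planted genes and is deterministic", {
  cfg <- sim_config(n_subjects = 350, n_genes = 25, n_informative_main = 2,
                    main_log_hr = c(0.8, -0.8), target_censoring_rate = 0.4,
                    covariate_log_hrs = c(age = 0.2, stage_score = 0.3),
                    seed = 61)
  coh <- simulate_cohort(cfg)
  x <- t(log2(unclass(coh$fpkm) + 1))
  covars <- coh$clinical[, setdiff(names(coh$clinical), "sample_id")]
  fc <- forest_config(n_trees = 100, min_node_size = 20, seed = 8)
  f <- fit_survival_forest(x, covars, coh$survival, fc)
  rk <- variable_importance(f)
  sw1 <- swsfs_select(x, covars, coh$survival, rk, fc, window = 3, k_max = 8)
  sw2 <- swsfs_select(x, covars, coh$survival, rk, fc, window = 3, k_max = 8)
  expect_identical(sw1, sw2)
  expect_lte(sw1$selected_k, 8L)
  planted <- rownames(coh$fpkm)[cfg$informative_idx]
  expect_true(all(planted %in% sw1$selected_genes))
  expect_equal(sw1$curve$smoothed_error,
               sliding_window_smooth(sw1$curve$oob_error, 3))
})

test_that("degenerate forest inputs are rejected", {
  pc <- planted_cohort(1, n = 50, n_genes = 4)
  no_event <- pc$outcome; no_event$event <- 0
  expect_error(fit_survival_forest(pc$x, pc$covars, no_event), "no events")
  expect_error(swsfs_select(pc$x, pc$covars, pc$outcome,
                            character(0)), "empty")
})
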