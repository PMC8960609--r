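test_that("exchangeable groups give a null hazard ratio", {
  # identical event-time multisets in both groups
  outc <- toy_outcome(time = c(1, 2, 3, 1, 2, 3), event = rep(1, 6))
  fit <- cox_fit(data.frame(group = c(0, 0, 0, 1, 1, 1)), outc)
  expect_equal(fit$coef[1], 0, tolerance = 1e-8)
  expect_equal(fit$hr[1], 1, tolerance = 1e-8)
})

test_that("cox_fit agrees with brute-force partial-likelihood maximization", {
  # 6-subject instance with distinct times
  x <- c(0.5, -1, 2, 0, 1.5, -0.3)
  outc <- toy_outcome(time = c(2, 5, 1, 8, 3, 6), event = c(1, 1, 1, 0, 1, 1))
  fit <- cox_fit(data.frame(x = x), outc)
  expect_equal(fit$coef[1], oracle_cox_beta(x, outc$time, outc$event),
               tolerance = 1e-4)

  # random instances up to 30 subjects, with ties (Efron correction)
  set.seed(8)
  for (i in 1:8) {
    n <- sample(8:30, 1)
    x <- rnorm(n)
    time <- sample(1:10, n, replace = TRUE)
    event <- rbinom(n, 1, 0.8)
    if (sum(event) < 2) next
    fit <- cox_fit(data.frame(x = x), toy_outcome(time, event))
    expect_equal(fit$coef[1], oracle_cox_beta(x, time, event), tolerance = 1e-4)
  }
})

test_that("a true two-group hazard ratio of 2 is recovered at n = 2000", {
  set.seed(3)
  n <- 2000
  g <- rep(0:1, each = n / 2)
  time <- rexp(n, exp(log(2) * g))
  outc <- toy_outcome(time, rep(1, n))
  fit <- cox_fit(data.frame(g = g), outc)
  expect_gt(fit$hr[1], 1.85); expect_lt(fit$hr[1], 2.16)
  expect_equal(fit$coef[1], oracle_cox_beta(g, time, outc$event), tolerance = 1e-6)
  # Wald CI brackets the HR
  expect_lt(fit$ci_low[1], fit$hr[1]); expect_gt(fit$ci_high[1], fit$hr[1])
})

test_that("negating a covariate inverts its hazard ratio and swaps CI bounds", {
  set.seed(4)
  x <- rnorm(60); time <- rexp(60, exp(0.5 * x))
  outc <- toy_outcome(time, rbinom(60, 1, 0.8))
  f1 <- cox_fit(data.frame(x = x), outc)
  f2 <- cox_fit(data.frame(x = -x), outc)
  expect_equal(f2$hr[1], 1 / f1$hr[1], tolerance = 1e-6)
  expect_equal(f2$ci_low[1], 1 / f1$ci_high[1], tolerance = 1e-6)
  expect_equal(f2$ci_high[1], 1 / f1$ci_low[1], tolerance = 1e-6)
})

test_that("degenerate Cox inputs are reported", {
  outc <- toy_outcome(c(1, 2, 3, 4), c(1, 1, 0, 1))
  expect_error(cox_fit(data.frame(x = rep(1, 4)), outc), "constant")
  expect_error(cox_fit(data.frame(x = 1:4), toy_outcome(1:4, rep(0, 4))),
               "no events")
  x <- c(1, 2, 3, 4)
  expect_error(cox_fit(data.frame(a = x, b = 2 * x), outc), "collinear")
})

test_that("BH adjustment follows the step-up formula", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  expect_equal(bh_fdr(0.037), 0.037)
  expect_equal(bh_fdr(c(0.001, 1.0)), c(0.002, 1.0))
  # monotone in sorted order; permutation-invariant
  set.seed(11)
  p <- runif(40)
  q <- bh_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  perm <- sample(40)
  expect_equal(bh_fdr(p[perm]), q[perm])
  expect_error(bh_fdr(numeric(0)), "empty")
})

test_that("main-effect scan computes the FDR family over the scan and keeps going on failures", {
  pc <- planted_cohort(71, n = 200, n_genes = 12, main = 0.8, idx = 3L)
  x <- pc$x
  x[, 5] <- 1   # constant gene: per-gene failure, scan continues
  res <- main_effect_scan(x, colnames(x), pc$covars, pc$outcome)
  expect_equal(nrow(res), 12L)
  expect_false(res$converged[res$term == "GENE0005"])
  ok <- !is.na(res$p)
  expect_equal(res$q[ok], bh_fdr(res$p[ok]))
  expect_equal(res$direction, sign(res$coef))
  expect_equal(res$term[which.min(res$p)], "GENE0003")
})

test_that("interaction scan covers each unordered pair once, order-invariantly", {
  pc <- planted_cohort(72, n = 150, n_genes = 8)
  cand <- colnames(pc$x)[1:5]
  res <- interaction_scan(pc$x, cand, pc$covars, pc$outcome)
  expect_equal(nrow(res), choose(5, 2))
  expect_false(any(duplicated(res$term)))
  res_rev <- interaction_scan(pc$x, rev(cand), pc$covars, pc$outcome)
  expect_equal(res, res_rev)
})

test_that("a planted interaction attains the smallest product-term p", {
  cfg <- sim_config(n_subjects = 500, n_genes = 12, interaction_pair = c(5, 9),
                    interaction_log_hr = 0.8, interaction_main_log_hrs = c(-0.3, 0.3),
                    covariate_log_hrs = c(age = 0.2), target_censoring_rate = 0.4,
                    seed = 55)
  coh <- simulate_cohort(cfg)
  x <- t(log2(unclass(coh$fpkm) + 1))
  covars <- coh$clinical[, setdiff(names(coh$clinical), "sample_id")]
  res <- interaction_scan(x, colnames(x), covars, coh$survival)
  expect_equal(res$term[which.min(res$p)], "GENE0005:GENE0009")
  expect_lt(res$q[which.min(res$p)], 0.05)
})

test_that("the sensitivity intersection requires joint significance and agreeing direction", {
  base <- data.frame(term = c("A", "B", "C", "D"),
                     hr = c(1.5, 1.5, 0.7, 1.2), coef = log(c(1.5, 1.5, 0.7, 1.2)),
                     direction = c(1, 1, -1, 1), stringsAsFactors = FALSE)
  fpkm <- cbind(base, q = c(0.01, 0.01, 0.04, 0.30))
  tmm <- base
  tmm$direction <- c(1, 1, 1, 1)
  tmm <- cbind(tmm, q = c(0.01, 0.30, 0.04, 0.01))
  keep <- sensitivity_intersection(fpkm, tmm)
  expect_identical(keep$term, "A")              # B: one branch ns; C: flip; D: ns
  expect_equal(keep$q_fpkm, 0.01)
  keep2 <- sensitivity_intersection(fpkm, tmm, require_direction = FALSE)
  expect_setequal(keep2$term, c("A", "C"))
  # term present in one branch only is excluded and logged
  keep3 <- sensitivity_intersection(fpkm, tmm[tmm$term != "A", ])
  expect_true("A" %in% attr(keep3, "excluded"))
})
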