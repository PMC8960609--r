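test_that("risk scores are the linear predictor of the fitted model", {
  set.seed(1)
  x <- rnorm(100); y <- rnorm(100)
  outc <- toy_outcome(rexp(100, exp(0.5 * x)), rbinom(100, 1, 0.8))
  fit <- cox_fit(data.frame(x = x, y = y), outc)
  des <- data.frame(x = c(1, 0, -2), y = c(0, 2, 1))
  expect_equal(risk_score(fit, des),
               as.numeric(fit$coef[1] * des$x + fit$coef[2] * des$y))
  # shifting a covariate shifts all scores equally (ranks unchanged)
  des2 <- des; des2$x <- des2$x + 5
  expect_equal(risk_score(fit, des2) - risk_score(fit, des),
               rep(5 * fit$coef[1], 3))
  expect_equal(order(risk_score(fit, des2)), order(risk_score(fit, des)))
  expect_error(risk_score(fit, des["x"]), "lacks model term")
})

test_that("time-dependent AUC matches exhaustive pair enumeration when uncensored", {
  # 5-subject toy: scores perfectly anti-rank times, horizon splits 2 vs 3
  outc <- toy_outcome(time = 1:5, event = rep(1, 5))
  res <- td_auc(scores = c(5, 4, 3, 2, 1), outc, horizon = 2.5)
  expect_equal(res$auc, 1)
  expect_equal(res$roc$tp[res$roc$fp == 0][3], 1)  # both cases found at fp = 0

  set.seed(14)
  for (i in 1:8) {
    n <- sample(30:100, 1)
    score <- sample(8, n, replace = TRUE)       # heavy score ties
    time <- rexp(n, exp(0.3 * score))
    h <- unname(quantile(time, runif(1, 0.3, 0.7)))
    res <- td_auc(score, toy_outcome(time, rep(1, n)), h)
    expect_equal(res$auc, oracle_auc_pairs(score, time, h), tolerance = 1e-12)
  }
})

test_that("AUC is invariant to strictly increasing score transforms and null-centred", {
  set.seed(15)
  n <- 400
  score <- rnorm(n)
  time <- rexp(n, exp(0.8 * score))
  event <- rbinom(n, 1, 0.8)
  outc <- toy_outcome(time, event)
  h <- unname(quantile(time, 0.5))
  a1 <- td_auc(score, outc, h)$auc
  a2 <- td_auc(exp(3 * score) + 2, outc, h)$auc
  expect_equal(a1, a2, tolerance = 1e-12)
  expect_gt(a1, 0.65)

  set.seed(16)
  null_scores <- rnorm(2000)
  tnull <- rexp(2000)
  anull <- td_auc(null_scores, toy_outcome(tnull, rbinom(2000, 1, 0.7)),
                  unname(quantile(tnull, 0.5)))$auc
  expect_gt(anull, 0.46); expect_lt(anull, 0.54)
})

test_that("td_auc rejects horizons without cases or controls", {
  outc <- toy_outcome(time = 1:5, event = rep(1, 5))
  expect_error(td_auc(5:1, outc, 0.5), "no cases")
  expect_error(td_auc(5:1, outc, 6), "no controls")
})

test_that("product-limit table matches hand computation on the 5-subject toy", {
  outc <- toy_outcome(time = 1:5, event = c(1, 0, 1, 0, 1))
  km <- km_survival(outc)
  expect_equal(km$survival, c(0.8, 0.8, 0.8 * (2 / 3), 0.8 * (2 / 3), 0),
               tolerance = 1e-12)
  # against the looped oracle at every time point
  set.seed(17)
  time <- sample(1:8, 10, replace = TRUE); event <- rbinom(10, 1, 0.6)
  km2 <- km_survival(toy_outcome(time, event))
  for (i in seq_len(nrow(km2)))
    expect_equal(km2$survival[i], oracle_km(time, event, km2$time[i]),
                 tolerance = 1e-12)
})

test_that("km_curve reports group survival, HR and log-rank; no-event edge survives", {
  set.seed(18)
  g <- rep(c("low", "high"), each = 40)
  time <- rexp(80, ifelse(g == "high", 0.3, 1))
  outc <- toy_outcome(time, rep(1, 80))
  kc <- km_curve(outc, g)
  # factor levels sort to (high, low): the reported HR is low vs high,
  # and the "low" group was given the higher hazard
  expect_gt(kc$hr_unadjusted$hr, 1)
  expect_lt(kc$logrank_p, 0.01)

  none <- km_curve(toy_outcome(time = 1:6, event = rep(0, 6)),
                   rep(c("a", "b"), 3))
  expect_true(all(none$table$survival == 1))
  expect_true(is.na(none$logrank_p))
  expect_error(km_curve(outc, rep("a", 80)), "two groups")
})

test_that("exchangeable groups give near-null log-rank behaviour", {
  set.seed(19)
  ps <- replicate(20, {
    time <- rexp(60); g <- sample(rep(0:1, 30))
    km_curve(toy_outcome(time, rep(1, 60)), g)$logrank_p
  })
  expect_gt(mean(ps > 0.05), 0.75)    # roughly uniform p-values
})

test_that("dichotomize applies median and fixed cutoffs with ties going low", {
  d <- dichotomize(c(1, 2, 3, 4), "median")
  expect_identical(as.character(d), c("low", "low", "high", "high"))
  expect_equal(attr(d, "cut"), 2.5)
  d2 <- dichotomize(c(2, 3.26, 5), 3.26)
  expect_identical(as.character(d2), c("low", "low", "high"))
  expect_error(dichotomize(rep(1, 5), "median"), "identical")
})

test_that("modifier strata reproduce the association fit on each subset", {
  cfg <- sim_config(n_subjects = 400, n_genes = 10, interaction_pair = c(3, 7),
                    interaction_log_hr = 1.2, interaction_main_log_hrs = c(-0.5, 0.2),
                    covariate_log_hrs = c(age = 0.2), target_censoring_rate = 0.4,
                    seed = 91)
  coh <- simulate_cohort(cfg)
  x <- t(log2(unclass(coh$fpkm) + 1))
  covars <- coh$clinical[, setdiff(names(coh$clinical), "sample_id")]
  ma <- modifier_analysis(x, "GENE0003", "GENE0007", covars, coh$survival)
  # internal consistency: stratum rows equal a direct scan on the subset
  gb <- dichotomize(x[, "GENE0007"], "median")
  for (lv in c("low", "high")) {
    idx <- which(gb == lv)
    direct <- main_effect_scan(x[idx, , drop = FALSE], "GENE0003",
                               covars[idx, , drop = FALSE],
                               coh$survival[idx, , drop = FALSE])
    row <- ma$strata[ma$strata$modifier_group == lv, ]
    expect_equal(row$hr, direct$hr, tolerance = 1e-12)
    expect_equal(row$p, direct$p, tolerance = 1e-12)
  }
  # a strong planted qualitative interaction separates the stratum HRs
  expect_true(xor(ma$strata$hr[1] < 1, ma$strata$hr[2] < 1) ||
                abs(log(ma$strata$hr[1] / ma$strata$hr[2])) > 0.3)
  expect_false(is.null(ma$km_four_group))
  expect_equal(length(unique(ma$km_four_group$table$group)), 4L)
})

test_that("bootstrap AUC comparison is deterministic and null for identical models", {
  set.seed(20)
  n <- 150
  x <- rnorm(n); z <- rnorm(n)
  time <- rexp(n, exp(0.7 * x)); event <- rbinom(n, 1, 0.8)
  outc <- toy_outcome(time, event)
  basic <- data.frame(x = x)
  h <- unname(quantile(time, 0.5))
  same <- bootstrap_auc_compare(basic, basic, outc, h, n_boot = 50, seed = 4)
  expect_equal(same$delta, 0)
  expect_gt(same$p, 0.9)
  expect_true(same$ci[1] <= 0 && same$ci[2] >= 0)

  opt <- cbind(basic, z = z)
  r1 <- bootstrap_auc_compare(basic, opt, outc, h, n_boot = 40, seed = 9)
  r2 <- bootstrap_auc_compare(basic, opt, outc, h, n_boot = 40, seed = 9)
  expect_identical(r1[c("ci", "p", "delta")], r2[c("ci", "p", "delta")])
  expect_equal(r1$relative_improvement,
               (r1$auc_optimized - r1$auc_basic) / r1$auc_basic)
})
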