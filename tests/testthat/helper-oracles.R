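# Independent brute-force oracles. These deliberately re-derive each
# quantity from first principles (loops, enumeration, closed forms) and are
# never shared with the package implementation.

# Efron partial log-likelihood for a single-coefficient Cox model.
oracle_partial_loglik <- function(beta, x, time, event) {
  eta <- beta * x
  ll <- 0
  for (t in unique(time[event == 1])) {
    D <- which(time == t & event == 1)
    R <- which(time >= t)
    d <- length(D)
    sumD <- sum(exp(eta[D]))
    sumR <- sum(exp(eta[R]))
    ll <- ll + sum(eta[D])
    for (l in seq_len(d)) {
      ll <- ll - log(sumR - (l - 1) / d * sumD)
    }
  }
  ll
}

# 1-D maximizer of the hand-coded partial likelihood.
oracle_cox_beta <- function(x, time, event, interval = c(-8, 8)) {
  stats::optimize(function(b) oracle_partial_loglik(b, x, time, event),
                  interval = interval, maximum = TRUE, tol = 1e-10)$maximum
}

# All-pairs concordance error, ties at one half, double loop.
oracle_concordance_error <- function(score, time, event) {
  n <- length(time); num <- 0; den <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (time[i] == time[j]) next
    a <- if (time[i] < time[j]) i else j
    b <- if (time[i] < time[j]) j else i
    if (event[a] != 1) next
    den <- den + 1
    num <- num + if (score[a] > score[b]) 1 else if (score[a] == score[b]) 0.5 else 0
  }
  1 - num / den
}

# AUC at a horizon on uncensored data: exhaustive case-control pairs.
oracle_auc_pairs <- function(score, time, horizon) {
  cases <- which(time <= horizon)
  controls <- which(time > horizon)
  tot <- 0
  for (i in cases) for (j in controls) {
    tot <- tot + if (score[i] > score[j]) 1 else if (score[i] == score[j]) 0.5 else 0
  }
  tot / (length(cases) * length(controls))
}

# Product-limit estimator by explicit looping over event times.
oracle_km <- function(time, event, at) {
  s <- 1
  for (t in sort(unique(time[event == 1]))) {
    if (t > at) break
    d <- sum(time == t & event == 1)
    r <- sum(time >= t)
    s <- s * (1 - d / r)
  }
  s
}

# TMM scaling factors, hand-coded from the published double-trimmed
# precision-weighted mean of M values formula.
oracle_tmm <- function(counts, ref, trim_m = 0.30, trim_a = 0.05) {
  lib <- colSums(counts)
  p_ref <- counts[, ref] / lib[ref]
  f <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    if (j == ref) { f[j] <- 1; next }
    p_j <- counts[, j] / lib[j]
    use <- p_j > 0 & p_ref > 0
    M <- log2(p_j[use] / p_ref[use])
    A <- (log2(p_j[use]) + log2(p_ref[use])) / 2
    w <- (lib[j] - counts[use, j]) / (lib[j] * counts[use, j]) +
      (lib[ref] - counts[use, ref]) / (lib[ref] * counts[use, ref])
    if (max(abs(M)) < 1e-6) { f[j] <- 1; next }
    # rank-based double trim, boundaries as in the published method:
    # drop the lowest/highest floor(n * trim) by M rank and by A rank
    nG <- length(M)
    loM <- floor(nG * trim_m) + 1; hiM <- nG + 1 - loM
    loA <- floor(nG * trim_a) + 1; hiA <- nG + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    f[j] <- 2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  }
  f / exp(mean(log(f)))
}

# Small helpers used across test files --------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_outcome <- function(time, event) data.frame(
  sample_id = sprintf("S%02d", seq_along(time)), time = time, event = event)

# A small planted-signal cohort on the modeling scale.
planted_cohort <- function(seed, n = 300, n_genes = 20, main = 1,
                           idx = 1L, censor = 0.4) {
  cfg <- sim_config(n_subjects = n, n_genes = n_genes,
                    n_informative_main = length(idx), informative_idx = idx,
                    main_log_hr = main, target_censoring_rate = censor,
                    covariate_log_hrs = c(age = 0.2, stage_score = 0.3),
                    seed = seed)
  coh <- simulate_cohort(cfg)
  list(x = t(log2(unclass(coh$fpkm) + 1)),
       covars = coh$clinical[, setdiff(names(coh$clinical), "sample_id")],
       outcome = coh$survival, cfg = cfg)
}
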