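#' Linear-predictor risk score of a fitted Cox model
#'
#' `score = sum(coef * term value)`; higher scores mean higher hazard. The
#' design must carry every model term (same names, same scale as at fit
#' time).
#'
#' @param fit a [cox_fit()] result.
#' @param design data.frame/matrix with the model's term columns.
#' @return numeric vector of scores.
#' @export
risk_score <- function(fit, design) {
  design <- as.data.frame(design, check.names = FALSE)
  missing <- setdiff(fit$term, names(design))
  if (length(missing) > 0)
    stop("design lacks model term(s): ", paste(missing, collapse = ", "))
  as.numeric(as.matrix(design[, fit$term, drop = FALSE]) %*% fit$coef)
}

km_weights <- function(time, event, horizon, group_order) {
  # Kaplan-Meier survival at `horizon` for every score-ordered prefix
  # {top-1}, {top-2}, ... {top-n} of the cohort, vectorized over prefixes.
  n <- length(time)
  et <- sort(unique(time[event == 1 & time <= horizon]))
  if (length(et) == 0) return(rep(1, n))
  t_ord <- time[group_order]; e_ord <- event[group_order]
  atrisk <- vapply(et, function(s) cumsum(t_ord >= s), numeric(n))     # n x |et|
  deaths <- vapply(et, function(s) cumsum(t_ord == s & e_ord == 1), numeric(n))
  frac <- 1 - deaths / pmax(atrisk, 1)
  frac[atrisk == 0] <- 1
  exp(rowSums(log(frac)))
}

#' Time-dependent ROC curve and AUC (cumulative cases, dynamic controls)
#'
#' Estimates sensitivity and specificity for discriminating subjects who
#' fail by the horizon (cumulative cases) from those surviving past it
#' (dynamic controls), handling censoring through Kaplan-Meier estimates of
#' S(horizon) overall and conditional on the score exceeding each cut
#' point: `TP(c) = (1 - S(t | X > c)) P(X > c) / (1 - S(t))`,
#' `FP(c) = S(t | X > c) P(X > c) / S(t)`. The AUC is the trapezoidal
#' integral over all score cut points. On uncensored data this reduces to
#' the empirical ROC, with tied scores contributing one half.
#'
#' @param scores numeric risk scores (higher = higher hazard).
#' @param outcome data.frame with `time`, `event`.
#' @param horizon prediction horizon (same units as `time`).
#' @return list with `auc` and `roc` (data.frame cutoff, tp, fp).
#' @export
td_auc <- function(scores, outcome, horizon) {
  time <- outcome$time; event <- outcome$event
  n <- length(scores)
  stopifnot(n == length(time))
  if (!any(event == 1 & time <= horizon)) stop("no cases by the horizon")
  if (!any(time > horizon)) stop("no controls past the horizon")
  ord <- order(-scores, time)           # descending score
  s_prefix <- km_weights(time, event, horizon, ord)
  s_overall <- s_prefix[n]
  if (s_overall <= 0 || s_overall >= 1)
    stop("overall survival at the horizon is degenerate")
  # cut points between distinct score values: prefix sizes at tie-group ends
  sc_ord <- scores[ord]
  last_of_group <- which(c(sc_ord[-n] != sc_ord[-1], TRUE))
  p_prefix <- last_of_group / n
  s_at <- s_prefix[last_of_group]
  tp <- (1 - s_at) * p_prefix / (1 - s_overall)
  fp <- s_at * p_prefix / s_overall
  tp <- c(0, tp); fp <- c(0, fp)
  auc <- sum(diff(fp) * (utils::head(tp, -1) + utils::tail(tp, -1)) / 2)
  list(auc = auc,
       roc = data.frame(cutoff = c(Inf, sc_ord[last_of_group]), tp = tp, fp = fp))
}

#' Bootstrap comparison of basic and optimized risk models by
#' time-dependent AUC
#'
#' The basic model uses covariates only; the optimized model adds the
#' selected expression terms. Both models are refit in every bootstrap
#' replicate (resampling subjects with replacement) and the AUC difference
#' at the horizon is recomputed, giving a percentile 95% CI and a two-sided
#' sign-flip p-value with a +1/(B+1) continuity correction. Replicates with
#' degenerate fits or no cases/controls at the horizon are skipped and
#' counted; more than 10% skipped aborts.
#'
#' @param basic_design,optimized_design model term data.frames (the
#'   optimized design must contain every basic column).
#' @param outcome data.frame with `time`, `event`.
#' @param horizon prediction horizon.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @return list with `horizon`, `auc_basic`, `auc_optimized`, `delta`,
#'   `relative_improvement`, `ci` (length-2), `p`, `n_boot_used`,
#'   `n_skipped`.
#' @export
bootstrap_auc_compare <- function(basic_design, optimized_design, outcome,
                                  horizon, n_boot = 1000, seed = 1L) {
  basic_design <- as.data.frame(basic_design, check.names = FALSE)
  optimized_design <- as.data.frame(optimized_design, check.names = FALSE)
  if (!all(names(basic_design) %in% names(optimized_design)))
    stop("optimized model terms must contain the basic model terms")
  one <- function(bd, od, oc) {
    # a rare indicator can go constant within a resample; drop it there
    # (its coefficient is undefined on that replicate) rather than skip
    keep <- vapply(bd, function(v) length(unique(v)) > 1L, logical(1))
    bd <- bd[, keep, drop = FALSE]
    keep_o <- vapply(od, function(v) length(unique(v)) > 1L, logical(1))
    od <- od[, keep_o, drop = FALSE]
    fb <- cox_fit(bd, oc)
    ab <- td_auc(risk_score(fb, bd), oc, horizon)$auc
    extra <- !identical(sort(names(od)), sort(names(bd)))
    ao <- if (extra) {
      fo <- cox_fit(od, oc)
      td_auc(risk_score(fo, od), oc, horizon)$auc
    } else ab
    c(ab, ao)
  }
  point <- one(basic_design, optimized_design, outcome)
  n <- nrow(outcome)
  set.seed(derive_seed(seed, "auc-bootstrap"))
  deltas <- numeric(0); skipped <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    res <- tryCatch(one(basic_design[idx, , drop = FALSE],
                        optimized_design[idx, , drop = FALSE],
                        outcome[idx, , drop = FALSE]),
                    error = function(e) NULL)
    if (is.null(res)) skipped <- skipped + 1L else deltas <- c(deltas, res[2] - res[1])
  }
  if (skipped > 0.10 * n_boot)
    stop(sprintf("too many degenerate bootstrap replicates (%d of %d)",
                 skipped, n_boot))
  ci <- unname(stats::quantile(deltas, c(0.025, 0.975), type = 7))
  p <- 2 * min((sum(deltas <= 0) + 1) / (length(deltas) + 1),
               (sum(deltas >= 0) + 1) / (length(deltas) + 1))
  list(horizon = horizon, auc_basic = point[1], auc_optimized = point[2],
       delta = point[2] - point[1],
       relative_improvement = (point[2] - point[1]) / point[1],
       ci = ci, p = min(p, 1), n_boot_used = length(deltas),
       n_skipped = skipped)
}

#' Product-limit survival table for a single cohort
#'
#' @param outcome data.frame with `time`, `event`.
#' @return data.frame `time`, `n_risk`, `n_event`, `survival` at every
#'   observed time (censoring times included).
#' @export
km_survival <- function(outcome) {
  sf <- survival::survfit(survival::Surv(outcome$time, outcome$event) ~ 1)
  ss <- summary(sf, censored = TRUE)
  data.frame(time = ss$time, n_risk = ss$n.risk, n_event = ss$n.event,
             survival = ss$surv)
}

#' Kaplan-Meier curves by group with hazard ratio and log-rank test
#'
#' Product-limit estimates per group (via \code{survival::survfit}),
#' between-group Cox hazard ratios (unadjusted, and covariate-adjusted when
#' covariates are supplied) and the log-rank test.
#'
#' @param outcome data.frame with `time`, `event`.
#' @param groups factor/character group labels (>= 2 levels).
#' @param covariates optional covariate data.frame for the adjusted HR.
#' @return list with `table` (group, time, n_risk, n_event, survival),
#'   `hr_unadjusted`, `hr_adjusted` (or NA), `logrank_p`.
#' @export
km_curve <- function(outcome, groups, covariates = NULL) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) stop("need at least two groups")
  df <- data.frame(time = outcome$time, event = outcome$event, group = groups)
  sf <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  ss <- summary(sf, censored = TRUE)
  tab <- data.frame(group = sub("^group=", "", as.character(ss$strata)),
                    time = ss$time, n_risk = ss$n.risk, n_event = ss$n.event,
                    survival = ss$surv, stringsAsFactors = FALSE)
  if (sum(outcome$event) == 0)
    return(list(table = tab, hr_unadjusted = NULL, hr_adjusted = NULL,
                logrank_p = NA_real_))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  logrank_p <- stats::pchisq(sd$chisq, df = length(sd$n) - 1, lower.tail = FALSE)
  des <- data.frame(group = as.numeric(groups == levels(droplevels(groups))[2]))
  names(des) <- paste0("group_", levels(droplevels(groups))[2])
  hr_u <- cox_fit(des, outcome)
  hr_a <- if (!is.null(covariates) && ncol(covariates) > 0)
    cox_fit(cbind(des, as.data.frame(covariate_design(covariates))), outcome)[1, ]
  else NULL
  list(table = tab, hr_unadjusted = hr_u[1, ], hr_adjusted = hr_a,
       logrank_p = logrank_p)
}

#' Split a continuous variable into low/high groups
#'
#' `rule = "median"` cuts at the sample median; a numeric rule is a fixed
#' cutoff applied verbatim. Ties at the cut go to the low group
#' (low: value <= cut, high: value > cut).
#'
#' @param values numeric vector.
#' @param rule `"median"` or a numeric cutoff.
#' @return factor with levels `low`, `high`; the cut is stored in the
#'   `cut` attribute.
#' @export
dichotomize <- function(values, rule = "median") {
  if (identical(rule, "median")) {
    if (length(unique(values)) == 1) stop("all values identical: median split undefined")
    cut <- stats::median(values)
  } else {
    stopifnot(is.numeric(rule), length(rule) == 1)
    cut <- rule
  }
  out <- factor(ifelse(values <= cut, "low", "high"), levels = c("low", "high"))
  attr(out, "cut") <- cut
  out
}

#' Effect-modifier analysis of a gene pair
#'
#' Dichotomizes the modifier gene (`gene_b`), refits the covariate-adjusted
#' main-effect model of `gene_a` within each modifier stratum, and builds
#' the four-group (gene_a low/high x gene_b low/high) Kaplan-Meier tables.
#'
#' @param features samples x genes matrix (modeling scale).
#' @param gene_a,gene_b gene ids; `gene_b` is the modifier.
#' @param covariates clinical covariate data.frame or NULL.
#' @param outcome survival data.frame.
#' @param rule_b dichotomization rule for the modifier (default
#'   `"median"`).
#' @return list with `strata` (per-stratum focal fit of gene_a),
#'   `cut_b`, and `km_four_group`.
#' @export
modifier_analysis <- function(features, gene_a, gene_b, covariates, outcome,
                              rule_b = "median") {
  stopifnot(all(c(gene_a, gene_b) %in% colnames(features)))
  gb <- dichotomize(features[, gene_b], rule_b)
  rows <- lapply(levels(gb), function(lv) {
    idx <- which(gb == lv)
    if (length(idx) == 0) stop("empty modifier stratum: ", lv)
    res <- tryCatch(
      main_effect_scan(features[idx, , drop = FALSE], gene_a,
                       if (is.null(covariates)) NULL else
                         covariates[idx, , drop = FALSE],
                       outcome[idx, , drop = FALSE],
                       phase = paste0(gene_b, "_", lv)),
      error = function(e) e)
    if (inherits(res, "error"))
      return(data.frame(modifier_group = lv, term = gene_a, hr = NA,
                        ci_low = NA, ci_high = NA, p = NA, n = length(idx),
                        error = conditionMessage(res), stringsAsFactors = FALSE))
    data.frame(modifier_group = lv, term = gene_a, hr = res$hr,
               ci_low = res$ci_low, ci_high = res$ci_high, p = res$p,
               n = length(idx), error = NA_character_, stringsAsFactors = FALSE)
  })
  ga <- dichotomize(features[, gene_a], "median")
  four <- interaction(ga, gb, sep = "_")
  km4 <- tryCatch(km_curve(outcome, four), error = function(e) NULL)
  list(strata = do.call(rbind, rows), cut_b = attr(gb, "cut"),
       km_four_group = km4)
}
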