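#' Choose surrogate genes on the validation platform
#'
#' A target measured on the validation platform is its own (identity)
#' surrogate. For an unmeasured target, Pearson correlation (on the
#' modeling scale, in the discovery data — the only place target and
#' candidate are jointly observed) is computed against every discovery gene
#' also present on the validation platform; correlation p-values are BH-FDR
#' adjusted per target, and the surrogate is the gene with maximal |r|
#' among those with q at or below `q_threshold` (|r| ties broken by gene
#' id). Targets with no eligible gene are reported unvalidatable.
#'
#' @param targets character vector of discovery gene ids.
#' @param discovery_features samples x genes matrix on the modeling scale.
#' @param validation_gene_set gene ids measured on the validation platform.
#' @param q_threshold correlation FDR threshold (default 0.05).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return data.frame `target`, `surrogate`, `r`, `p`, `q`, `is_identity`,
#'   `validatable`.
#' @export
find_surrogates <- function(targets, discovery_features, validation_gene_set,
                            q_threshold = 0.05, method = "pearson") {
  stopifnot(all(targets %in% colnames(discovery_features)),
            length(validation_gene_set) > 0)
  rows <- lapply(targets, function(tg) {
    if (stats::sd(discovery_features[, tg]) == 0)
      stop("zero-variance target gene: ", tg)
    if (tg %in% validation_gene_set)
      return(data.frame(target = tg, surrogate = tg, r = 1, p = 0, q = 0,
                        is_identity = TRUE, validatable = TRUE,
                        stringsAsFactors = FALSE))
    cands <- setdiff(intersect(colnames(discovery_features), validation_gene_set), tg)
    if (length(cands) == 0)
      return(data.frame(target = tg, surrogate = NA_character_, r = NA, p = NA,
                        q = NA, is_identity = FALSE, validatable = FALSE,
                        stringsAsFactors = FALSE))
    ct <- lapply(cands, function(g)
      stats::cor.test(discovery_features[, tg], discovery_features[, g],
                      method = method, exact = FALSE))
    r <- vapply(ct, function(x) unname(x$estimate), numeric(1))
    p <- vapply(ct, function(x) x$p.value, numeric(1))
    q <- bh_fdr(pmin(pmax(p, .Machine$double.xmin), 1))
    ok <- q <= q_threshold & !is.na(r)
    if (!any(ok))
      return(data.frame(target = tg, surrogate = NA_character_, r = NA, p = NA,
                        q = NA, is_identity = FALSE, validatable = FALSE,
                        stringsAsFactors = FALSE))
    pick <- which(ok)[order(-abs(r[ok]), cands[ok])][1L]
    data.frame(target = tg, surrogate = cands[pick], r = r[pick], p = p[pick],
               q = q[pick], is_identity = FALSE, validatable = TRUE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Confirm discovery hits on the validation platform
#'
#' Refits the main-effect or interaction hazard model on the validation
#' dataset with each discovery gene replaced by its surrogate, and passes a
#' term only when (1) the focal-term p-value is at or below `p_threshold`
#' in the validation phase and (2) the focal-term effect direction agrees
#' across phases. Direction consistency applies to the focal term only
#' (constituent main terms of an interaction may differ across platforms).
#'
#' @param discovery_results retained scan rows (main and/or interaction;
#'   needs `analysis`, `term`, and for interactions `gene1`, `gene2`,
#'   plus `direction`).
#' @param surrogate_map a [find_surrogates()] data.frame.
#' @param validation_features samples x genes matrix (modeling scale) on
#'   the validation platform.
#' @param covariates validation clinical covariates (or NULL).
#' @param outcome validation survival data.frame.
#' @param p_threshold nominal validation significance level (default 0.05).
#' @return data.frame, one row per term: validation statistics, `passed`,
#'   `reason`.
#' @export
validate_terms <- function(discovery_results, surrogate_map,
                           validation_features, covariates, outcome,
                           p_threshold = 0.05) {
  smap <- stats::setNames(surrogate_map$surrogate, surrogate_map$target)
  ok <- stats::setNames(surrogate_map$validatable, surrogate_map$target)
  rows <- lapply(seq_len(nrow(discovery_results)), function(i) {
    d <- discovery_results[i, ]
    genes <- if (identical(d$analysis, "interaction")) c(d$gene1, d$gene2) else d$term
    base <- data.frame(analysis = d$analysis, term = d$term,
                       discovery_hr = d$hr, discovery_direction = d$direction,
                       stringsAsFactors = FALSE)
    if (any(!genes %in% names(smap)) || any(!ok[genes])) {
      return(cbind(base, data.frame(surrogates = NA, validation_hr = NA,
                                    validation_p = NA, validation_direction = NA,
                                    passed = FALSE, reason = "no eligible surrogate",
                                    stringsAsFactors = FALSE)))
    }
    sg <- smap[genes]
    res <- tryCatch({
      if (identical(d$analysis, "interaction"))
        interaction_scan(validation_features, unname(sg), covariates, outcome,
                         phase = "validation")
      else
        main_effect_scan(validation_features, unname(sg), covariates, outcome,
                         phase = "validation")
    }, error = function(e) e)
    if (inherits(res, "error") || all(is.na(res$p)))
      return(cbind(base, data.frame(surrogates = paste(sg, collapse = ":"),
                                    validation_hr = NA, validation_p = NA,
                                    validation_direction = NA, passed = FALSE,
                                    reason = if (inherits(res, "error"))
                                      conditionMessage(res) else res$error[1],
                                    stringsAsFactors = FALSE)))
    v <- res[1, ]
    sig <- !is.na(v$p) && v$p <= p_threshold
    consistent <- !is.na(v$direction) && v$direction == d$direction
    reason <- if (sig && consistent) "validated" else if (!sig)
      sprintf("validation p > %g", p_threshold) else "direction flip"
    cbind(base, data.frame(surrogates = paste(sg, collapse = ":"),
                           validation_hr = v$hr, validation_p = v$p,
                           validation_direction = v$direction,
                           passed = sig && consistent, reason = reason,
                           stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Histology-stratified refit of focal models
#'
#' Refits the focal main-effect or interaction model within each histology
#' stratum (histology is dropped from the within-stratum covariates).
#' Strata where the events-per-coefficient ratio falls below
#' `min_events_per_coef` are flagged unstable.
#'
#' @param results rows to refit (same layout as scan output).
#' @param features samples x genes matrix.
#' @param covariates clinical covariates including a `histology` column.
#' @param outcome survival data.frame.
#' @param min_events_per_coef stability rule (default 10).
#' @return data.frame with one row per term x stratum.
#' @export
stratified_analysis <- function(results, features, covariates, outcome,
                                min_events_per_coef = 10) {
  stopifnot("histology" %in% names(covariates))
  strata <- sort(unique(as.character(covariates$histology)))
  rows <- list()
  for (st in strata) {
    idx <- which(as.character(covariates$histology) == st)
    if (length(idx) == 0) stop("empty histology stratum: ", st)
    cov_st <- covariates[idx, setdiff(names(covariates), "histology"), drop = FALSE]
    out_st <- outcome[idx, , drop = FALSE]
    feat_st <- features[idx, , drop = FALSE]
    for (i in seq_len(nrow(results))) {
      d <- results[i, ]
      res <- tryCatch({
        if (identical(d$analysis, "interaction"))
          interaction_scan(feat_st, c(d$gene1, d$gene2), cov_st, out_st,
                           phase = paste0("stratum:", st))
        else
          main_effect_scan(feat_st, d$term, cov_st, out_st,
                           phase = paste0("stratum:", st))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        rows[[length(rows) + 1]] <- data.frame(
          stratum = st, analysis = d$analysis, term = d$term, hr = NA,
          ci_low = NA, ci_high = NA, p = NA, n = length(idx),
          n_events = sum(out_st$event), unstable = TRUE,
          error = conditionMessage(res), stringsAsFactors = FALSE)
        next
      }
      v <- res[1, ]
      n_coef <- if (identical(d$analysis, "interaction")) 3 else 1
      n_coef <- n_coef + ncol(covariate_design(cov_st))
      rows[[length(rows) + 1]] <- data.frame(
        stratum = st, analysis = d$analysis, term = v$term, hr = v$hr,
        ci_low = v$ci_low, ci_high = v$ci_high, p = v$p, n = length(idx),
        n_events = sum(out_st$event),
        unstable = sum(out_st$event) < min_events_per_coef * n_coef,
        error = NA_character_, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
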