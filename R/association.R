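#' Covariate-adjusted Cox proportional-hazards fit
#'
#' Wraps \code{survival::coxph} (Efron tie handling by default, Newton
#' iterations to machine-level tolerance) and returns per-term hazard
#' ratios with Wald 95% confidence intervals. Collinear terms (dropped by
#' the fitter) and non-convergence are reported as errors rather than
#' silently passed through.
#'
#' @param design numeric matrix or data.frame of model terms (samples in
#'   rows).
#' @param outcome data.frame with `time`, `event`, row-aligned.
#' @param ties tie-handling method, `"efron"` or `"breslow"`.
#' @return a `cox_fit` data.frame: one row per term with `term`, `coef`,
#'   `se`, `hr`, `ci_low`, `ci_high`, `p`; attributes `n`, `n_events`,
#'   `converged`, `loglik`.
#' @export
cox_fit <- function(design, outcome, ties = "efron") {
  design <- as.data.frame(design, check.names = FALSE)
  stopifnot(nrow(design) == nrow(outcome))
  if (sum(outcome$event) < 1) stop("no events: Cox model undefined")
  const <- vapply(design, function(v) length(unique(v)) <= 1L, logical(1))
  if (any(const))
    stop("constant model term(s): ", paste(names(design)[const], collapse = ", "))
  if (qr(as.matrix(design))$rank < ncol(design))
    stop("collinear model terms: the design matrix is rank deficient")
  dat <- cbind(design, .time = outcome$time, .event = outcome$event)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(design)), collapse = " + ")))
  warn <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = ties),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  co <- stats::coef(fit)
  if (any(is.na(co)))
    stop("collinear model term(s) dropped by the fitter: ",
         paste(names(co)[is.na(co)], collapse = ", "))
  if (any(abs(co) > 15))
    warning("diverging coefficient (monotone likelihood?) for: ",
            paste(names(co)[abs(co) > 15], collapse = ", "))
  se <- sqrt(diag(fit$var))
  z <- co / se
  out <- data.frame(term = gsub("`", "", names(co)),
                    coef = as.numeric(co), se = as.numeric(se),
                    hr = exp(as.numeric(co)),
                    ci_low = exp(as.numeric(co) - 1.96 * se),
                    ci_high = exp(as.numeric(co) + 1.96 * se),
                    p = 2 * stats::pnorm(-abs(z)),
                    stringsAsFactors = FALSE)
  attr(out, "n") <- fit$n
  attr(out, "n_events") <- fit$nevent
  attr(out, "converged") <-
    !any(grepl("converge|infinite|beta may be infinite|out of iterations",
               warn, ignore.case = TRUE))
  attr(out, "loglik") <- fit$loglik[2]
  class(out) <- c("cox_fit", "data.frame")
  out
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1 and
#' returned in the input order (delegates to \code{stats::p.adjust}).
#'
#' @param p vector of p-values in (0, 1].
#' @return q-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) stop("empty p-value vector")
  stopifnot(all(p > 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

scan_covariate_design <- function(covariates) {
  if (is.null(covariates) || ncol(covariates) == 0) return(NULL)
  covariate_design(covariates)
}

#' Main-effect association scan (one gene at a time)
#'
#' For each candidate gene fits the hazard model
#' `h(t) = h0(t) exp(a1 * gene + sum(b_i * covariate_i))` on the modeling
#' scale and reports the focal gene term with BH-FDR q computed across the
#' scan. Per-gene fit failures are recorded and the scan continues.
#'
#' @param features samples x genes matrix (modeling scale).
#' @param candidates character vector of gene ids to test.
#' @param covariates clinical covariate data.frame or NULL.
#' @param outcome data.frame with `time`, `event`.
#' @param phase label stored with the results (`"discovery"` or
#'   `"validation"`).
#' @return data.frame, one row per gene: `term`, `hr`, `ci_low`, `ci_high`,
#'   `coef`, `p`, `q`, `direction`, `n`, `n_events`, `converged`, `error`.
#' @export
main_effect_scan <- function(features, candidates, covariates, outcome,
                             phase = "discovery") {
  stopifnot(length(candidates) >= 1, all(candidates %in% colnames(features)))
  cd <- scan_covariate_design(covariates)
  rows <- lapply(candidates, function(g) {
    des <- cbind(stats::setNames(data.frame(features[, g]), g),
                 as.data.frame(cd))
    res <- tryCatch(cox_fit(des, outcome), error = function(e) e)
    if (inherits(res, "error"))
      return(data.frame(term = g, hr = NA, ci_low = NA, ci_high = NA,
                        coef = NA, p = NA, n = NA, n_events = NA,
                        converged = FALSE, error = conditionMessage(res),
                        stringsAsFactors = FALSE))
    foc <- res[res$term == g, ]
    data.frame(term = g, hr = foc$hr, ci_low = foc$ci_low,
               ci_high = foc$ci_high, coef = foc$coef, p = foc$p,
               n = attr(res, "n"), n_events = attr(res, "n_events"),
               converged = attr(res, "converged"), error = NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  if (any(ok)) out$q[ok] <- bh_fdr(out$p[ok])
  out$direction <- sign(out$coef)
  out$analysis <- "main"
  out$phase <- phase
  out[, c("analysis", "phase", "term", "hr", "ci_low", "ci_high", "coef",
          "p", "q", "direction", "n", "n_events", "converged", "error")]
}

#' Pairwise interaction scan over all unordered candidate pairs
#'
#' For every unordered pair (g1, g2) fits
#' `h(t) = h0(t) exp(a1 g1 + a2 g2 + a3 g1*g2 + sum(b_i covariate_i))`; the
#' focal term is the product `g1:g2` and BH-FDR q is computed across the
#' C(k,2) pairs.
#'
#' @inheritParams main_effect_scan
#' @return data.frame, one row per pair, with `gene1`, `gene2`, `term` and
#'   the same statistics columns as [main_effect_scan()].
#' @export
interaction_scan <- function(features, candidates, covariates, outcome,
                             phase = "discovery") {
  stopifnot(length(candidates) >= 2, all(candidates %in% colnames(features)))
  candidates <- sort(unique(candidates))
  cd <- scan_covariate_design(covariates)
  pairs <- utils::combn(candidates, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    pname <- paste(g1, g2, sep = ":")
    des <- data.frame(features[, g1], features[, g2],
                      features[, g1] * features[, g2])
    names(des) <- c(g1, g2, pname)
    des <- cbind(des, as.data.frame(cd))
    res <- tryCatch(cox_fit(des, outcome), error = function(e) e)
    if (inherits(res, "error"))
      return(data.frame(gene1 = g1, gene2 = g2, term = pname, hr = NA,
                        ci_low = NA, ci_high = NA, coef = NA, p = NA,
                        n = NA, n_events = NA, converged = FALSE,
                        error = conditionMessage(res), stringsAsFactors = FALSE))
    foc <- res[res$term == pname, ]
    data.frame(gene1 = g1, gene2 = g2, term = pname, hr = foc$hr,
               ci_low = foc$ci_low, ci_high = foc$ci_high, coef = foc$coef,
               p = foc$p, n = attr(res, "n"), n_events = attr(res, "n_events"),
               converged = attr(res, "converged"), error = NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  if (any(ok)) out$q[ok] <- bh_fdr(out$p[ok])
  out$direction <- sign(out$coef)
  out$analysis <- "interaction"
  out$phase <- phase
  out[, c("analysis", "phase", "gene1", "gene2", "term", "hr", "ci_low",
          "ci_high", "coef", "p", "q", "direction", "n", "n_events",
          "converged", "error")]
}

#' Sensitivity intersection of two normalization branches
#'
#' A term is carried forward only if it is simultaneously significant
#' (FDR-q at or below the threshold) in both the FPKM branch and the
#' TMM-normalized count branch, and (optionally) its effect direction
#' agrees across branches.
#'
#' @param results_fpkm,results_tmm scan results indexed by `term`.
#' @param q_threshold FDR significance threshold (default 0.05).
#' @param require_direction also require sign agreement of the focal
#'   coefficient (default TRUE).
#' @return the FPKM-branch rows of retained terms, with `q_fpkm`, `q_tmm`
#'   columns; attribute `excluded` lists terms present in only one branch.
#' @export
sensitivity_intersection <- function(results_fpkm, results_tmm,
                                     q_threshold = 0.05,
                                     require_direction = TRUE) {
  common <- intersect(results_fpkm$term, results_tmm$term)
  only <- c(setdiff(results_fpkm$term, common), setdiff(results_tmm$term, common))
  a <- results_fpkm[match(common, results_fpkm$term), ]
  b <- results_tmm[match(common, results_tmm$term), ]
  keep <- !is.na(a$q) & !is.na(b$q) & a$q <= q_threshold & b$q <= q_threshold
  if (require_direction) keep <- keep & (a$direction == b$direction)
  out <- a[keep, , drop = FALSE]
  out$q_fpkm <- a$q[keep]
  out$q_tmm <- b$q[keep]
  rownames(out) <- NULL
  attr(out, "excluded") <- only
  out
}
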