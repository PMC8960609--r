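#' Derive a reproducible stage seed from a pipeline seed
#'
#' All stochastic stages draw their seed from a single pipeline seed plus a
#' stage counter, so any stage can be re-run in isolation and reproduce the
#' full-pipeline result.
#'
#' @param seed integer master seed.
#' @param counter non-negative integer stage counter (or a short string,
#'   hashed to a counter).
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, counter) {
  if (is.character(counter)) {
    counter <- sum(utf8ToInt(counter) * seq_along(utf8ToInt(counter))) %% 100003L
  }
  stopifnot(is.numeric(seed), length(seed) == 1L)
  ((as.double(seed) %% 2147483647) * 48271 + as.double(counter) * 16807 + 11) %%
    2147483647
}

#' Harrell concordance error with ties counted one half
#'
#' Computes `1 - C` where C is the concordance index between a risk score
#' (higher = higher hazard) and right-censored outcomes. A pair (i, j) is
#' comparable when the smaller observed time belongs to an event. Tied scores
#' contribute 0.5; pairs with tied event times are not comparable.
#'
#' @param score numeric risk scores.
#' @param time observed times.
#' @param event 0/1 event indicators.
#' @return error in `[0, 1]`; 0.5 means no discrimination.
#' @export
concordance_error <- function(score, time, event) {
  stopifnot(length(score) == length(time), length(time) == length(event))
  keep <- !is.na(score)
  score <- score[keep]; time <- time[keep]; event <- event[keep]
  n <- length(time)
  num <- 0; den <- 0
  # O(n^2) but vectorized over j; n is a few hundred at most where this runs
  for (i in seq_len(n)) {
    if (event[i] != 1) next
    later <- time > time[i]
    if (!any(later)) next
    den <- den + sum(later)
    num <- num + sum(score[i] > score[later]) + 0.5 * sum(score[i] == score[later])
  }
  if (den == 0) stop("no comparable pairs: concordance undefined")
  1 - num / den
}

#' Reference-coded design matrix for clinical covariates
#'
#' Continuous covariates pass through unchanged; factors and character
#' columns are expanded to 0/1 indicators against the most frequent level
#' (ties broken alphabetically), so the encoding is deterministic for a given
#' table.
#'
#' @param clinical data.frame of covariates (no id column).
#' @param drop_constant drop columns with a single observed value.
#' @return numeric matrix, one row per sample.
#' @export
covariate_design <- function(clinical, drop_constant = TRUE) {
  stopifnot(is.data.frame(clinical))
  cols <- list()
  for (nm in names(clinical)) {
    x <- clinical[[nm]]
    if (is.numeric(x)) {
      cols[[nm]] <- as.numeric(x)
    } else {
      x <- as.character(x)
      tab <- sort(table(x), decreasing = TRUE)
      lev <- names(tab)
      ref <- sort(lev[tab == max(tab)])[1L]
      for (l in setdiff(lev, ref)) {
        cols[[paste(nm, l, sep = "_")]] <- as.numeric(x == l)
      }
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- rownames(clinical)
  if (drop_constant && ncol(m) > 0) {
    keep <- apply(m, 2, function(v) length(unique(v)) > 1L)
    m <- m[, keep, drop = FALSE]
  }
  m
}

z_score <- function(x) {
  s <- stats::sd(x)
  if (is.na(s) || s == 0) return(x - mean(x))
  (x - mean(x)) / s
}
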