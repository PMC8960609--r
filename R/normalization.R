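#' Trimmed-mean-of-M-values (TMM) scaling factors
#'
#' Computes between-sample scaling factors for count libraries by the TMM
#' method of Robinson & Oshlack: per-gene log ratios (M) and average log
#' abundances (A) against a reference library are double-trimmed (30% on M,
#' 5% on A by default) and combined as a precision-weighted mean, with the
#' reference chosen as the library whose upper quartile of nonzero relative
#' abundances is closest to the mean upper quartile. Factors are rescaled to
#' geometric mean 1. The computation is delegated to
#' \code{edgeR::calcNormFactors}, the method's reference implementation.
#'
#' @param counts an [expression_matrix()] with unit `counts`, at least two
#'   samples, all library totals positive.
#' @param trim_m two-sided trim proportion on M values.
#' @param trim_a two-sided trim proportion on A values.
#' @return data.frame `sample_id`, `factor`, with attribute
#'   `reference_sample_id`.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  if (expr_unit(counts) != "counts") stop("TMM requires a counts matrix")
  if (ncol(counts) < 2) stop("TMM needs at least two samples")
  libsize <- colSums(counts)
  if (any(libsize <= 0)) stop("zero-count library: ",
                              paste(colnames(counts)[libsize <= 0], collapse = ", "))
  m <- unclass(counts)
  # reference library: upper quartile of nonzero relative abundance closest
  # to the mean (edgeR's rule); ties to the lexicographically smallest id
  uq <- apply(sweep(m, 2, libsize, "/"), 2, function(x) stats::quantile(x[x > 0], 0.75))
  ord <- order(abs(uq - mean(uq)), colnames(m))
  ref <- ord[1L]
  f <- edgeR::calcNormFactors(m, method = "TMM", refColumn = ref,
                              logratioTrim = trim_m, sumTrim = trim_a,
                              doWeighting = TRUE)
  out <- data.frame(sample_id = colnames(m), factor = as.numeric(f),
                    stringsAsFactors = FALSE)
  attr(out, "reference_sample_id") <- colnames(m)[ref]
  out
}

#' Apply scaling factors to counts on a counts-per-million scale
#'
#' value -> value / (library_total * factor) * 1e6. The result is a
#' normalized continuous matrix (unit `fpkm`, i.e. non-negative reals) ready
#' for the log2(x+1) transform.
#'
#' @param counts an [expression_matrix()] with unit `counts`.
#' @param factors output of [tmm_factors()] (or any sample_id/factor table).
#' @return an [expression_matrix()] of normalized values.
#' @export
apply_factors <- function(counts, factors) {
  missing <- setdiff(colnames(counts), factors$sample_id)
  if (length(missing) > 0)
    stop("no scaling factor for sample(s): ", paste(missing, collapse = ", "))
  f <- factors$factor[match(colnames(counts), factors$sample_id)]
  eff <- colSums(counts) * f
  expression_matrix(sweep(unclass(counts), 2, eff, "/") * 1e6, "fpkm")
}
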