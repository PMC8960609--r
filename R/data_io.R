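#' Expression matrix container
#'
#' A genes x samples numeric matrix with a unit tag. Counts must be
#' non-negative integers, fpkm non-negative reals; log2 values are
#' unconstrained. Duplicate gene or sample ids are rejected.
#'
#' @param values numeric matrix, genes in rows.
#' @param unit one of `"counts"`, `"fpkm"`, `"log2"`.
#' @return an object of class `expr_matrix` (a matrix with a `unit`
#'   attribute).
#' @export
expression_matrix <- function(values, unit = c("counts", "fpkm", "log2")) {
  unit <- match.arg(unit)
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  finite <- values[!is.na(values)]
  if (unit == "counts") {
    if (any(finite < 0) || any(finite != round(finite)))
      stop("unit violation: counts must be non-negative integers")
  } else if (unit == "fpkm") {
    if (any(finite < 0)) stop("unit violation: fpkm values must be non-negative")
  }
  structure(values, unit = unit, class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expression matrix [%s]: %d genes x %d samples\n",
              attr(x, "unit"), nrow(x), ncol(x)))
  invisible(x)
}

expr_unit <- function(x) attr(x, "unit")

#' Read / write an expression matrix as TSV
#'
#' Tab-delimited text with a `gene_id` first column and one column per
#' sample. The write/read round trip is value-identical to printed precision.
#'
#' @param path file path.
#' @param unit the unit the file stores (validated on read).
#' @return `read_expression` returns an [expression_matrix()].
#' @export
read_expression <- function(path, unit = c("counts", "fpkm", "log2")) {
  unit <- match.arg(unit)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "gene_id") stop("first column must be 'gene_id'")
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene ids in ", path, ": ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$gene_id
  expression_matrix(m, unit)
}

#' @rdname read_expression
#' @param matrix an [expression_matrix()].
#' @export
write_expression <- function(matrix, path) {
  df <- data.frame(gene_id = rownames(matrix), as.data.frame(unclass(matrix)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Gene-level quality-control filter
#'
#' Removes genes whose expression is zero in every sample, and genes whose
#' proportion of missing values exceeds `max_missing` (strictly greater:
#' exactly 10\% missing is kept under the default).
#'
#' @param matrix an [expression_matrix()].
#' @param max_missing maximum tolerated missing proportion (default 0.10).
#' @return list with `matrix` (filtered) and `removed` (data.frame of
#'   gene_id, reason).
#' @export
qc_filter_genes <- function(matrix, max_missing = 0.10) {
  miss <- rowMeans(is.na(matrix))
  allzero <- vapply(seq_len(nrow(matrix)), function(i) {
    v <- matrix[i, ]
    all(!is.na(v)) && all(v == 0)
  }, logical(1))
  toomiss <- miss > max_missing
  drop <- allzero | toomiss
  reason <- ifelse(allzero, "all zero",
                   ifelse(toomiss, sprintf("missing %.1f%% > %.1f%%",
                                           100 * miss, 100 * max_missing), NA))
  removed <- data.frame(gene_id = rownames(matrix)[drop],
                        reason = reason[drop], stringsAsFactors = FALSE)
  kept <- matrix[!drop, , drop = FALSE]
  if (nrow(kept) == 0L) warning("QC removed every gene")
  list(matrix = expression_matrix(unclass(kept), expr_unit(matrix)),
       removed = removed)
}

#' Sample-level quality-control alignment
#'
#' Keeps the samples present in the expression matrix, the clinical table and
#' the survival outcome that have complete clinical covariates, and returns
#' the three inputs restricted to that intersection in a canonical (sorted
#' id) order.
#'
#' @param matrix an [expression_matrix()].
#' @param clinical data.frame with a `sample_id` column.
#' @param outcome data.frame with `sample_id`, `time`, `event`.
#' @return list with `matrix`, `clinical`, `outcome`, and `dropped`
#'   (data.frame of sample_id, reason).
#' @export
qc_filter_samples <- function(matrix, clinical, outcome) {
  stopifnot("sample_id" %in% names(clinical), "sample_id" %in% names(outcome))
  common <- intersect(intersect(colnames(matrix), clinical$sample_id),
                      outcome$sample_id)
  if (length(common) == 0L) stop("no samples shared by expression, clinical and outcome")
  complete <- clinical$sample_id[stats::complete.cases(clinical)]
  keep <- sort(intersect(common, complete))
  if (length(keep) == 0L) stop("no samples with complete clinical covariates")
  all_ids <- unique(c(colnames(matrix), clinical$sample_id, outcome$sample_id))
  dropped <- setdiff(all_ids, keep)
  reason <- ifelse(dropped %in% common, "incomplete clinical covariates",
                   "absent from one or more inputs")
  ci <- clinical[match(keep, clinical$sample_id), , drop = FALSE]
  oi <- outcome[match(keep, outcome$sample_id), , drop = FALSE]
  rownames(ci) <- rownames(oi) <- NULL
  list(matrix = expression_matrix(unclass(matrix[, keep, drop = FALSE]),
                                  expr_unit(matrix)),
       clinical = ci, outcome = oi,
       dropped = data.frame(sample_id = dropped, reason = reason,
                            stringsAsFactors = FALSE))
}

#' log2(x + 1) transform of a non-negative expression matrix
#'
#' @param matrix an [expression_matrix()] with unit `fpkm` or `counts`
#'   (e.g. normalized counts on a CPM-like scale).
#' @return an [expression_matrix()] with unit `log2`.
#' @export
log_transform <- function(matrix) {
  if (expr_unit(matrix) == "log2") stop("matrix is already on the log2 scale")
  if (any(matrix[!is.na(matrix)] < 0)) stop("negative values cannot be log transformed")
  expression_matrix(log2(unclass(matrix) + 1), "log2")
}

#' Read / write clinical and survival tables as CSV
#'
#' @param path file path.
#' @return data.frame; survival tables are checked for positive times and
#'   0/1 events.
#' @export
read_clinical <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("clinical table needs a sample_id column")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in clinical table")
  df
}

#' @rdname read_clinical
#' @export
read_survival <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% names(df))) stop("survival table needs sample_id, time, event")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in survival table")
  if (any(df$time <= 0)) stop("survival times must be positive")
  if (!all(df$event %in% c(0, 1))) stop("event must be 0/1")
  df
}
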