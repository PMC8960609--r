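#' Configuration for the covariate-forced random survival forest
#'
#' @param n_trees trees in the ensemble.
#' @param mtry genes sampled as split candidates per node, or `"sqrt"`.
#' @param min_node_size minimal terminal node size.
#' @param covariates_forced if TRUE every covariate is a split candidate at
#'   every node, in addition to the `mtry` sampled genes, so each tree is
#'   adjusted for all covariates.
#' @param seed integer seed.
#' @return a `forest_config` list.
#' @export
forest_config <- function(n_trees = 1000, mtry = "sqrt", min_node_size = 15,
                          covariates_forced = TRUE, seed = 1L) {
  stopifnot(n_trees >= 1, min_node_size >= 1)
  structure(list(n_trees = as.integer(n_trees), mtry = mtry,
                 min_node_size = as.integer(min_node_size),
                 covariates_forced = isTRUE(covariates_forced),
                 seed = as.integer(seed)), class = "forest_config")
}

resolve_mtry <- function(mtry, n_genes) {
  if (identical(mtry, "sqrt")) mtry <- floor(sqrt(n_genes))
  mtry <- max(1L, min(as.integer(mtry), n_genes))
  mtry
}

#' Fit a covariate-forced random survival forest
#'
#' Grows a `ranger` survival forest on gene features plus clinical
#' covariates. With `covariates_forced` (the default) the covariates are
#' passed as always-available split candidates (`always.split.variables`),
#' so every node of every tree considers all of them alongside the `mtry`
#' sampled genes; this is the structural realization of giving each
#' covariate full selection weight. Covariates enter as a reference-coded
#' numeric design so the encoding matches the downstream Cox models.
#'
#' @param features samples x genes numeric matrix (modeling scale).
#' @param covariates data.frame of clinical covariates (no id column), or
#'   NULL.
#' @param outcome data.frame with `time` and `event`, row-aligned with
#'   `features`.
#' @param config a [forest_config()].
#' @param importance compute permutation variable importance (TRUE for the
#'   ranking forest; the SWSFS refits skip it, as only the OOB error is
#'   needed there).
#' @return a `surv_forest` list: the ranger object, feature/covariate names,
#'   the outcome, and the per-sample OOB mortality (summed OOB ensemble
#'   cumulative hazard).
#' @export
fit_survival_forest <- function(features, covariates, outcome, config = forest_config(),
                                importance = TRUE) {
  stopifnot(nrow(features) == nrow(outcome))
  if (ncol(features) < 1) stop("no gene features supplied")
  if (sum(outcome$event) < 1) stop("no events: forest cannot be fit")
  if (length(unique(outcome$time)) == 1) stop("constant outcome time")
  gene_names <- colnames(features)
  cov_design <- if (is.null(covariates) || ncol(covariates) == 0) NULL else
    covariate_design(covariates)
  dat <- data.frame(features, check.names = FALSE)
  if (!is.null(cov_design)) dat <- cbind(dat, as.data.frame(cov_design))
  dat$.time <- outcome$time
  dat$.event <- outcome$event
  always <- if (config$covariates_forced && !is.null(cov_design)) colnames(cov_design) else NULL
  fit <- ranger::ranger(
    survival::Surv(.time, .event) ~ ., data = dat,
    num.trees = config$n_trees,
    mtry = resolve_mtry(config$mtry, length(gene_names)),
    min.node.size = config$min_node_size,
    always.split.variables = always,
    importance = if (importance) "permutation" else "none",
    keep.inbag = TRUE,
    num.threads = 1,
    seed = config$seed)
  mortality <- rowSums(fit$chf)   # ranger's chf on training data is OOB
  structure(list(fit = fit, gene_names = gene_names,
                 covariate_names = if (is.null(always)) colnames(cov_design) else always,
                 outcome = outcome, oob_mortality = mortality,
                 config = config), class = "surv_forest")
}

#' Permutation variable-importance ranking of genes
#'
#' Importance of a gene is the mean increase in out-of-bag error when its
#' out-of-bag values are permuted (Breiman permutation importance, as
#' computed by ranger on the survival C-index error). Covariates are
#' adjustment terms, not candidates, and are excluded from the ranking.
#' Ties are broken by gene id so the order is deterministic.
#'
#' @param forest a [fit_survival_forest()] result.
#' @return data.frame `gene_id`, `importance`, sorted descending.
#' @export
variable_importance <- function(forest) {
  imp <- forest$fit$variable.importance
  if (is.null(imp) || length(imp) == 0)
    stop("forest was fitted without permutation importance")
  imp <- imp[names(imp) %in% forest$gene_names]
  ord <- order(-imp, names(imp))
  data.frame(gene_id = names(imp)[ord], importance = as.numeric(imp[ord]),
             stringsAsFactors = FALSE)
}

#' Out-of-bag ensemble error of a survival forest
#'
#' One minus Harrell's concordance index between the out-of-bag ensemble
#' mortality (each sample's cumulative hazard summed over the trees in which
#' it was out of bag) and the observed outcomes, with tied predictions
#' counted one half.
#'
#' @param forest a [fit_survival_forest()] result.
#' @return error in `[0, 1]`.
#' @export
oob_error <- function(forest) {
  concordance_error(forest$oob_mortality, forest$outcome$time, forest$outcome$event)
}

#' Centered moving average used to smooth the OOB error curve
#'
#' @param x numeric vector.
#' @param window odd positive window width; truncated at the boundaries.
#' @return smoothed vector of the same length.
#' @export
sliding_window_smooth <- function(x, window = 5) {
  stopifnot(window >= 1, window %% 2 == 1)
  h <- (window - 1) / 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - h):min(n, i + h)])
  }, numeric(1))
}

#' Select k from a raw OOB error curve by windowed-minimum rule
#'
#' @param raw_errors OOB error at k = 1..K.
#' @param window smoothing window (odd).
#' @return list with `selected_k`, `smoothed` and `raw` curves.
#' @export
select_k_min_oob <- function(raw_errors, window = 5) {
  sm <- sliding_window_smooth(raw_errors, window)
  list(selected_k = which.min(sm), smoothed = sm, raw = raw_errors)
}

#' Sliding-window sequential forward feature selection (SWSFS)
#'
#' Adds genes one at a time in descending importance order, refits the
#' covariate-forced survival forest on the top-k genes for each k, records
#' the out-of-bag error, smooths the error curve with a centered moving
#' average, and selects the k attaining the minimal smoothed error (smallest
#' k on ties).
#'
#' @param features samples x genes matrix (modeling scale).
#' @param covariates clinical covariate data.frame or NULL.
#' @param outcome data.frame with `time`, `event`.
#' @param ranking a [variable_importance()] data.frame (or vector of gene
#'   ids in rank order).
#' @param config a [forest_config()]; each k gets a seed derived from it.
#' @param window odd smoothing window width.
#' @param k_max largest candidate-set size examined (capped at the ranking
#'   length; default `min(50, length(ranking))`).
#' @return list with `selected_genes`, `selected_k`, and `curve`
#'   (data.frame k, oob_error, smoothed_error).
#' @export
swsfs_select <- function(features, covariates, outcome, ranking,
                         config = forest_config(), window = 5, k_max = NULL) {
  genes <- if (is.data.frame(ranking)) ranking$gene_id else as.character(ranking)
  if (length(genes) == 0) stop("empty importance ranking")
  if (is.null(k_max)) k_max <- min(50L, length(genes))
  k_max <- min(as.integer(k_max), length(genes))
  if (k_max < 1) stop("k_max must be at least 1")
  raw <- numeric(k_max)
  for (k in seq_len(k_max)) {
    cfg_k <- config
    cfg_k$seed <- as.integer(derive_seed(config$seed, 1000L + k) %% 2147483646)
    f <- fit_survival_forest(features[, genes[seq_len(k)], drop = FALSE],
                             covariates, outcome, cfg_k, importance = FALSE)
    raw[k] <- oob_error(f)
  }
  sel <- select_k_min_oob(raw, window)
  list(selected_genes = genes[seq_len(sel$selected_k)],
       selected_k = sel$selected_k,
       curve = data.frame(k = seq_len(k_max), oob_error = raw,
                          smoothed_error = sel$smoothed))
}
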