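#' Pipeline configuration for the two-phase workflow
#'
#' @param q_threshold_discovery FDR threshold for the discovery scans and
#'   the sensitivity intersection.
#' @param p_threshold_validation nominal significance level for the
#'   validation phase.
#' @param forest a [forest_config()] for the importance-ranking forest.
#' @param swsfs_forest a [forest_config()] for the per-k SWSFS refits, or
#'   NULL to reuse `forest`. The error curve is smoothed across k, so these
#'   refits tolerate fewer trees than the ranking fit.
#' @param swsfs_window odd smoothing window for SWSFS.
#' @param k_max largest SWSFS candidate-set size examined.
#' @param horizons prediction horizons (years) for the AUC comparison.
#' @param n_boot bootstrap replicates for the AUC comparison.
#' @param max_missing gene-level QC missingness threshold.
#' @param transform `"log2p1"` (log2(x+1), default) or `"none"`.
#' @param require_direction direction agreement in the sensitivity
#'   intersection.
#' @param seed master pipeline seed; stage seeds derive from it.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(q_threshold_discovery = 0.05,
                            p_threshold_validation = 0.05,
                            forest = forest_config(),
                            swsfs_forest = NULL,
                            swsfs_window = 5,
                            k_max = 50,
                            horizons = c(3, 5),
                            n_boot = 1000,
                            max_missing = 0.10,
                            transform = c("log2p1", "none"),
                            require_direction = TRUE,
                            seed = 1L) {
  transform <- match.arg(transform)
  stopifnot(q_threshold_discovery > 0, q_threshold_discovery < 1,
            p_threshold_validation > 0, p_threshold_validation < 1,
            swsfs_window %% 2 == 1, k_max >= 1, n_boot >= 1)
  structure(list(q_threshold_discovery = q_threshold_discovery,
                 p_threshold_validation = p_threshold_validation,
                 forest = forest, swsfs_forest = swsfs_forest,
                 swsfs_window = swsfs_window,
                 k_max = as.integer(k_max), horizons = horizons,
                 n_boot = as.integer(n_boot), max_missing = max_missing,
                 transform = transform,
                 require_direction = isTRUE(require_direction),
                 seed = as.integer(seed)), class = "pipeline_config")
}

modeling_scale <- function(matrix, transform) {
  m <- if (identical(transform, "log2p1")) log_transform(matrix) else matrix
  t(unclass(m))   # samples x genes for the modeling stages
}

clinical_covariates <- function(clinical) {
  clinical[, setdiff(names(clinical), "sample_id"), drop = FALSE]
}

#' Run the discovery phase: QC, screening, testing, sensitivity
#'
#' Executes gene- and sample-level QC, builds the FPKM branch and the
#' TMM-normalized count branch, screens the FPKM branch with the
#' covariate-forced forest plus SWSFS, runs the main-effect and pairwise
#' interaction scans on both branches, and intersects them so only terms
#' simultaneously significant in both normalizations (with agreeing
#' directions) are carried forward.
#'
#' @param fpkm,counts [expression_matrix()] objects (genes x samples).
#' @param clinical clinical table with `sample_id`.
#' @param outcome survival table with `sample_id`, `time`, `event`.
#' @param config a [pipeline_config()].
#' @return a `discovery_report` list (QC log, ranking, OOB curve,
#'   candidates, per-branch scan results, retained terms, counts per
#'   stage).
#' @export
run_discovery <- function(fpkm, counts, clinical, outcome, config = pipeline_config()) {
  qg <- qc_filter_genes(fpkm, config$max_missing)
  qs <- qc_filter_samples(qg$matrix, clinical, outcome)
  n_in <- ncol(fpkm); g_in <- nrow(fpkm)
  fpkm_q <- qs$matrix
  counts_q <- expression_matrix(
    unclass(counts)[rownames(fpkm_q), colnames(fpkm_q), drop = FALSE], "counts")
  covars <- clinical_covariates(qs$clinical)
  outc <- qs$outcome

  x_fpkm <- modeling_scale(fpkm_q, config$transform)
  fac <- tmm_factors(counts_q)
  x_tmm <- modeling_scale(apply_factors(counts_q, fac), config$transform)

  fcfg <- config$forest
  fcfg$seed <- as.integer(derive_seed(config$seed, "screen") %% 2147483646)
  forest <- fit_survival_forest(x_fpkm, covars, outc, fcfg)
  ranking <- variable_importance(forest)
  scfg <- if (is.null(config$swsfs_forest)) fcfg else config$swsfs_forest
  scfg$seed <- fcfg$seed
  sw <- swsfs_select(x_fpkm, covars, outc, ranking, scfg,
                     window = config$swsfs_window, k_max = config$k_max)
  cand <- sw$selected_genes

  main_fpkm <- main_effect_scan(x_fpkm, cand, covars, outc)
  main_tmm <- main_effect_scan(x_tmm, cand, covars, outc)
  main_keep <- sensitivity_intersection(main_fpkm, main_tmm,
                                        config$q_threshold_discovery,
                                        config$require_direction)
  if (length(cand) >= 2) {
    int_fpkm <- interaction_scan(x_fpkm, cand, covars, outc)
    int_tmm <- interaction_scan(x_tmm, cand, covars, outc)
    int_keep <- sensitivity_intersection(int_fpkm, int_tmm,
                                         config$q_threshold_discovery,
                                         config$require_direction)
  } else {
    int_fpkm <- int_tmm <- int_keep <- NULL
  }
  structure(list(
    qc = list(genes_removed = qg$removed, samples_dropped = qs$dropped,
              n_samples = c(input = n_in, retained = ncol(fpkm_q)),
              n_genes = c(input = g_in, retained = nrow(fpkm_q))),
    clinical = qs$clinical, outcome = outc,
    features_fpkm = x_fpkm, features_tmm = x_tmm, tmm_factors = fac,
    ranking = ranking, oob_curve = sw$curve, candidates = cand,
    selected_k = sw$selected_k,
    main_fpkm = main_fpkm, main_tmm = main_tmm, main_retained = main_keep,
    interaction_fpkm = int_fpkm, interaction_tmm = int_tmm,
    interaction_retained = int_keep,
    config = config), class = "discovery_report")
}

retained_terms <- function(discovery) {
  rbind(
    if (!is.null(discovery$main_retained) && nrow(discovery$main_retained) > 0)
      cbind(discovery$main_retained[, c("analysis", "term", "hr", "coef",
                                        "p", "q", "direction")],
            gene1 = discovery$main_retained$term, gene2 = NA_character_),
    if (!is.null(discovery$interaction_retained) &&
        nrow(discovery$interaction_retained) > 0)
      cbind(discovery$interaction_retained[, c("analysis", "term", "hr", "coef",
                                               "p", "q", "direction")],
            gene1 = discovery$interaction_retained$gene1,
            gene2 = discovery$interaction_retained$gene2))
}

#' Run the validation phase: surrogates, confirmation, stratification,
#' model comparison
#'
#' Maps every retained discovery gene to a surrogate on the validation
#' platform, refits the focal models on the validation cohort, applies the
#' two confirmation criteria (nominal significance and direction
#' consistency), refits the confirmed terms within histology strata, and
#' compares the basic (covariates-only) and optimized (covariates +
#' confirmed expression terms) risk models by time-dependent AUC at the
#' configured horizons with bootstrap inference.
#'
#' @param discovery a [run_discovery()] report.
#' @param fpkm validation-platform [expression_matrix()].
#' @param clinical,outcome validation cohort tables.
#' @param config a [pipeline_config()] (defaults to the discovery one).
#' @return a `validation_report` list (surrogate map, verdicts, stratified
#'   fits, AUC comparisons, manifest).
#' @export
run_validation <- function(discovery, fpkm, clinical, outcome,
                           config = discovery$config) {
  terms <- retained_terms(discovery)
  qg <- qc_filter_genes(fpkm, config$max_missing)
  qs <- qc_filter_samples(qg$matrix, clinical, outcome)
  x_val <- modeling_scale(qs$matrix, config$transform)
  covars <- clinical_covariates(qs$clinical)
  outc <- qs$outcome

  if (is.null(terms) || nrow(terms) == 0) {
    empty <- list(surrogates = NULL, verdicts = NULL, stratified = NULL,
                  auc = NULL,
                  status = "no term survived the discovery phase",
                  manifest = pipeline_manifest(config))
    return(structure(empty, class = "validation_report"))
  }
  genes <- unique(stats::na.omit(c(terms$gene1, terms$gene2)))
  smap <- find_surrogates(genes, discovery$features_fpkm, colnames(x_val),
                          q_threshold = config$q_threshold_discovery)
  verdicts <- validate_terms(terms, smap, x_val, covars, outc,
                             p_threshold = config$p_threshold_validation)

  passed <- verdicts[verdicts$passed, , drop = FALSE]
  strat <- if (nrow(passed) > 0 && "histology" %in% names(covars))
    stratified_analysis(terms[terms$term %in% passed$term, , drop = FALSE],
                        x_val, covars, outc)
  else NULL

  auc <- NULL
  if (nrow(passed) > 0) {
    smap_named <- stats::setNames(smap$surrogate, smap$target)
    basic <- as.data.frame(covariate_design(covars))
    opt <- basic
    for (i in seq_len(nrow(passed))) {
      v <- passed[i, ]
      if (identical(v$analysis, "interaction")) {
        g1 <- smap_named[[terms$gene1[terms$term == v$term]]]
        g2 <- smap_named[[terms$gene2[terms$term == v$term]]]
        opt[[g1]] <- x_val[, g1]
        opt[[g2]] <- x_val[, g2]
        opt[[paste(g1, g2, sep = ":")]] <- x_val[, g1] * x_val[, g2]
      } else {
        g <- smap_named[[v$term]]
        opt[[g]] <- x_val[, g]
      }
    }
    auc <- lapply(config$horizons, function(h) {
      tryCatch(bootstrap_auc_compare(basic, opt, outc, h,
                                     n_boot = config$n_boot,
                                     seed = derive_seed(config$seed,
                                                        paste0("auc", h))),
               error = function(e) list(horizon = h,
                                        error = conditionMessage(e)))
    })
    names(auc) <- paste0("horizon_", config$horizons)
  }
  structure(list(surrogates = smap, verdicts = verdicts, stratified = strat,
                 auc = auc,
                 status = if (nrow(passed) > 0) "terms validated"
                          else "no term passed validation",
                 manifest = pipeline_manifest(config)),
            class = "validation_report")
}

pipeline_manifest <- function(config) {
  list(package_version = as.character(utils::packageVersion("survscreen")),
       r_version = R.version.string,
       seed = config$seed,
       config = unclass(config)[setdiff(names(unclass(config)),
                                        c("forest", "swsfs_forest"))],
       forest = unclass(config$forest),
       swsfs_forest = if (is.null(config$swsfs_forest)) NULL else
         unclass(config$swsfs_forest),
       timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
}
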