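#' Configuration for the synthetic two-platform survival study generator
#'
#' Describes a simulated cohort whose statistical structure mirrors a bulk
#' expression prognostic study: log-normal expression with block correlation
#' (so every gene has potential surrogates), a parallel raw-count matrix for
#' the count-normalization branch, clinical covariates with realistic
#' marginals, and Weibull proportional-hazards survival with independent
#' censoring calibrated to a target censoring rate. All hazard coefficients
#' are per standard deviation of the log2 expression scale.
#'
#' @param n_subjects cohort size.
#' @param n_genes number of expression features.
#' @param n_informative_main number of genes given a main effect.
#' @param main_log_hr log hazard ratio (per SD) for each informative gene;
#'   recycled to `n_informative_main`.
#' @param informative_idx indices of the main-effect genes, or `NULL` to
#'   place them in distinct correlation blocks (first gene of blocks 1, 2,
#'   ...), so planted effects do not cancel through shared block structure.
#' @param interaction_pair indices (1-based) of the interacting gene pair, or
#'   `NULL` for none. The pair genes are distinct from the main-effect genes
#'   and should sit in different blocks from them (and from each other).
#' @param interaction_log_hr log HR of the product term.
#' @param interaction_main_log_hrs length-2 log HRs for the pair genes' own
#'   main effects (constituent terms of the interaction model).
#' @param covariate_log_hrs named log HRs for the clinical covariates on the
#'   encoded scale (age per SD; indicators for male, current smoker, LUSC;
#'   stage as a linear 0-3 score).
#' @param baseline_shape,baseline_scale Weibull baseline hazard parameters
#'   (scale in years).
#' @param target_censoring_rate desired fraction censored, strictly in (0,1).
#' @param platform_overlap_fraction fraction of genes measured on the
#'   validation platform.
#' @param surrogate_correlation within-block latent correlation in (0,1).
#' @param block_size genes per correlated block.
#' @param mean_age,sd_age,mean_pack_years,sd_pack_years normal marginals for
#'   the continuous covariates.
#' @param gender_props,race_props,smoke_props,stage_props,histology_props
#'   named categorical proportions (must sum to 1 within 1e-6).
#' @param mean_depth expected library size for the count matrix.
#' @param seed integer seed; every draw derives from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_subjects = 600,
                       n_genes = 100,
                       n_informative_main = 0,
                       informative_idx = NULL,
                       main_log_hr = 0.5,
                       interaction_pair = NULL,
                       interaction_log_hr = 0,
                       interaction_main_log_hrs = c(0, 0),
                       covariate_log_hrs = c(age = 0.30, gender_Male = 0.15,
                                             smoke_status_Current = 0.10,
                                             stage_score = 0.45,
                                             histology_LUSC = 0.05),
                       baseline_shape = 1.2,
                       baseline_scale = 8,
                       target_censoring_rate = 0.596,
                       platform_overlap_fraction = 1.0,
                       surrogate_correlation = 0.9,
                       block_size = 2,
                       mean_age = 66.02, sd_age = 9.55,
                       mean_pack_years = 47.38, sd_pack_years = 29.96,
                       gender_props = c(Male = 0.5877, Female = 0.4123),
                       race_props = c(White = 0.8957, Black = 0.0911, Asian = 0.0132),
                       smoke_props = c(Former = 0.6887, Current = 0.3113),
                       stage_props = c(I = 0.543, II = 0.283, III = 0.146, IV = 0.028),
                       histology_props = c(LUAD = 0.4868, LUSC = 0.5132),
                       mean_depth = 2e5,
                       seed = 1L) {
  stopifnot(n_subjects >= 2, n_genes >= 1, n_informative_main >= 0,
            n_informative_main <= n_genes,
            target_censoring_rate > 0, target_censoring_rate < 1,
            platform_overlap_fraction > 0, platform_overlap_fraction <= 1,
            surrogate_correlation > 0, surrogate_correlation < 1,
            block_size >= 1, baseline_shape > 0, baseline_scale > 0)
  for (p in list(gender_props, race_props, smoke_props, stage_props, histology_props)) {
    if (abs(sum(p) - 1) > 1e-6)
      stop("categorical proportions must sum to 1 (got ", sum(p), ")")
    if (any(p < 0)) stop("negative category proportion")
  }
  main_log_hr <- rep_len(main_log_hr, max(n_informative_main, 1L))[seq_len(n_informative_main)]
  if (is.null(informative_idx)) {
    informative <- (seq_len(n_informative_main) - 1L) * block_size + 1L
    if (n_informative_main > 0 && max(informative) > n_genes)
      informative <- seq_len(n_informative_main)
  } else {
    informative <- as.integer(informative_idx)
    stopifnot(length(informative) == n_informative_main,
              all(informative >= 1), all(informative <= n_genes),
              !anyDuplicated(informative))
  }
  if (!is.null(interaction_pair)) {
    stopifnot(length(interaction_pair) == 2,
              interaction_pair[1] != interaction_pair[2],
              all(interaction_pair >= 1), all(interaction_pair <= n_genes))
    if (any(interaction_pair %in% informative))
      stop("interaction pair must not overlap the main-effect genes")
  }
  structure(list(
    n_subjects = as.integer(n_subjects), n_genes = as.integer(n_genes),
    n_informative_main = as.integer(n_informative_main),
    informative_idx = informative, main_log_hr = main_log_hr,
    interaction_pair = interaction_pair,
    interaction_log_hr = interaction_log_hr,
    interaction_main_log_hrs = rep_len(interaction_main_log_hrs, 2L),
    covariate_log_hrs = covariate_log_hrs,
    baseline_shape = baseline_shape, baseline_scale = baseline_scale,
    target_censoring_rate = target_censoring_rate,
    platform_overlap_fraction = platform_overlap_fraction,
    surrogate_correlation = surrogate_correlation,
    block_size = as.integer(block_size),
    mean_age = mean_age, sd_age = sd_age,
    mean_pack_years = mean_pack_years, sd_pack_years = sd_pack_years,
    gender_props = gender_props, race_props = race_props,
    smoke_props = smoke_props, stage_props = stage_props,
    histology_props = histology_props,
    mean_depth = mean_depth, seed = as.integer(seed)), class = "sim_config")
}

gene_ids <- function(n) sprintf("GENE%04d", seq_len(n))
sample_ids <- function(n, prefix = "S") sprintf("%s%04d", prefix, seq_len(n))

draw_categorical <- function(n, props) {
  factor(sample(names(props), n, replace = TRUE, prob = props), levels = names(props))
}

#' Simulate a clinical covariate table
#'
#' Age and pack-years are normal (pack-years truncated at zero); gender,
#' race, smoking status, clinical stage and histology are categorical with
#' the configured proportions. No values are missing.
#'
#' @param config a [sim_config()].
#' @return data.frame with one row per sample.
#' @export
simulate_covariates <- function(config) {
  set.seed(derive_seed(config$seed, "covariates"))
  n <- config$n_subjects
  data.frame(
    sample_id = sample_ids(n),
    age = stats::rnorm(n, config$mean_age, config$sd_age),
    gender = draw_categorical(n, config$gender_props),
    race = draw_categorical(n, config$race_props),
    smoke_status = draw_categorical(n, config$smoke_props),
    pack_years = pmax(stats::rnorm(n, config$mean_pack_years, config$sd_pack_years), 0),
    clinical_stage = draw_categorical(n, config$stage_props),
    histology = draw_categorical(n, config$histology_props),
    stringsAsFactors = FALSE)
}

#' Simulate block-correlated expression on two scales
#'
#' Latent per-gene values are Gaussian on the log2 scale, drawn block-wise
#' with compound-symmetric within-block correlation
#' `surrogate_correlation`, so each gene's block partners are its natural
#' surrogates. The FPKM-like matrix is the exponentiated latent (log-normal,
#' strictly positive); the count matrix is Poisson with per-sample library
#' sizes around `mean_depth` and per-gene intensities proportional to the
#' FPKM-like values.
#'
#' @param config a [sim_config()].
#' @return list with `fpkm` and `counts`, both [expression_matrix()] objects
#'   (genes x samples).
#' @export
simulate_expression <- function(config) {
  set.seed(derive_seed(config$seed, "expression"))
  n <- config$n_subjects; G <- config$n_genes; b <- config$block_size
  rho <- config$surrogate_correlation
  # compound-symmetric blocks; rho in (0,1) keeps them positive definite
  nblock <- ceiling(G / b)
  latent <- matrix(0, G, n)
  for (k in seq_len(nblock)) {
    idx <- ((k - 1) * b + 1):min(k * b, G)
    m <- length(idx)
    shared <- stats::rnorm(n)
    own <- matrix(stats::rnorm(m * n), m, n)
    latent[idx, ] <- sqrt(rho) * matrix(shared, m, n, byrow = TRUE) + sqrt(1 - rho) * own
  }
  mu <- stats::runif(G, 0.5, 3.5)      # log2-scale gene abundances
  latent <- latent + mu
  rownames(latent) <- gene_ids(G); colnames(latent) <- sample_ids(n)
  fpkm <- 2^latent
  depth <- stats::rlnorm(n, log(config$mean_depth), 0.2)
  rel <- sweep(fpkm, 2, colSums(fpkm), "/")
  counts <- matrix(stats::rpois(G * n, as.vector(sweep(rel, 2, depth, "*"))), G, n,
                   dimnames = dimnames(fpkm))
  list(fpkm = expression_matrix(fpkm, "fpkm"),
       counts = expression_matrix(counts, "counts"))
}

#' Simulate right-censored survival under a Weibull proportional-hazards model
#'
#' The linear predictor combines the configured per-SD gene effects (main
#' and product-term) computed on standardized log2 expression with the
#' covariate effects on the encoded clinical scale. Event times come from the
#' inverse-transform `T = scale * (-log U / exp(lp))^(1/shape)`; independent
#' uniform censoring times are calibrated by root finding on their scale so
#' the expected censoring rate matches `target_censoring_rate`.
#'
#' @param fpkm FPKM-like [expression_matrix()] (genes x samples).
#' @param clinical output of [simulate_covariates()].
#' @param config a [sim_config()].
#' @return data.frame `sample_id`, `time`, `event` plus attributes
#'   `linear_predictor` and `censor_scale`.
#' @export
simulate_survival <- function(fpkm, clinical, config) {
  stopifnot(identical(colnames(fpkm), clinical$sample_id))
  set.seed(derive_seed(config$seed, "survival"))
  n <- config$n_subjects
  logx <- log2(unclass(fpkm) + 1)
  zg <- function(i) z_score(logx[i, ])
  lp <- rep(0, n)
  for (j in seq_along(config$informative_idx))
    lp <- lp + config$main_log_hr[j] * zg(config$informative_idx[j])
  if (!is.null(config$interaction_pair)) {
    z1 <- zg(config$interaction_pair[1]); z2 <- zg(config$interaction_pair[2])
    lp <- lp + config$interaction_main_log_hrs[1] * z1 +
      config$interaction_main_log_hrs[2] * z2 +
      config$interaction_log_hr * z1 * z2
  }
  b <- config$covariate_log_hrs
  cov_vals <- list(
    age = z_score(clinical$age),
    gender_Male = as.numeric(clinical$gender == "Male"),
    smoke_status_Current = as.numeric(clinical$smoke_status == "Current"),
    stage_score = as.numeric(clinical$clinical_stage) - 1,
    histology_LUSC = as.numeric(clinical$histology == "LUSC"))
  for (nm in names(b)) {
    if (!nm %in% names(cov_vals)) stop("unknown covariate in covariate_log_hrs: ", nm)
    lp <- lp + b[[nm]] * cov_vals[[nm]]
  }
  u <- stats::runif(n)
  ev_time <- config$baseline_scale * (-log(u) / exp(lp))^(1 / config$baseline_shape)
  # uniform censoring C ~ U(0, cmax); expected censoring = mean(min(T/cmax, 1))
  target <- config$target_censoring_rate
  f <- function(cmax) mean(pmin(ev_time / cmax, 1)) - target
  lo <- stats::quantile(ev_time, 0.01); hi <- max(ev_time) * 100
  cmax <- tryCatch(stats::uniroot(f, c(lo, hi), tol = 1e-8)$root,
                   error = function(e) stats::quantile(ev_time, 1 - target) * 2)
  C <- stats::runif(n, 0, cmax)
  time <- pmin(ev_time, C); event <- as.numeric(ev_time <= C)
  if (all(event == 0)) stop("degenerate draw: every subject censored")
  if (all(event == 1)) stop("degenerate draw: no subject censored")
  out <- data.frame(sample_id = clinical$sample_id,
                    time = pmax(time, .Machine$double.eps), event = event,
                    stringsAsFactors = FALSE)
  attr(out, "linear_predictor") <- lp
  attr(out, "censor_scale") <- cmax
  out
}

#' Restrict a dataset to a partially overlapping validation platform
#'
#' The validation platform measures `floor(overlap * n_genes)` genes. When
#' `force_missing` is TRUE every ground-truth gene (main-effect and
#' interaction-pair) is deliberately dropped from the validation platform
#' while at least one of its block partners is kept, so the surrogate path
#' is exercised.
#'
#' @param fpkm discovery FPKM-like [expression_matrix()].
#' @param config a [sim_config()].
#' @param force_missing drop truth genes from the validation platform.
#' @return list with `discovery_genes`, `validation_genes`, and `truth`
#'   (informative ids, pair ids, coefficients, per-platform maps).
#' @export
split_platforms <- function(fpkm, config, force_missing = FALSE) {
  set.seed(derive_seed(config$seed, "platform"))
  ids <- rownames(fpkm); G <- length(ids)
  keep_n <- floor(config$platform_overlap_fraction * G)
  truth_idx <- c(config$informative_idx, config$interaction_pair)
  truth_ids <- ids[truth_idx]
  blocks <- split(seq_len(G), ceiling(seq_len(G) / config$block_size))
  partner_of <- function(i) {
    blk <- blocks[[ceiling(i / config$block_size)]]
    setdiff(blk, i)
  }
  if (force_missing && length(truth_idx) > 0) {
    partners <- unique(unlist(lapply(truth_idx, partner_of)))
    if (length(partners) == 0)
      stop("force_missing requires block_size >= 2 so surrogates exist")
    must_drop <- truth_idx
    must_keep <- setdiff(partners, truth_idx)
    if (length(must_keep) == 0)
      stop("no non-truth block partner available as surrogate")
    pool <- setdiff(seq_len(G), c(must_drop, must_keep))
    extra_keep <- keep_n - length(must_keep)
    if (extra_keep < 0) stop("platform overlap too low to keep surrogate partners")
    if (extra_keep > length(pool)) extra_keep <- length(pool)
    keep_idx <- sort(c(must_keep, sample(pool, extra_keep)))
  } else {
    keep_idx <- sort(sample(seq_len(G), keep_n))
  }
  if (length(keep_idx) == 0) stop("validation platform would carry no genes")
  truth <- list(
    informative_gene_ids = ids[config$informative_idx],
    main_log_hr = config$main_log_hr,
    interaction_pair_ids = if (is.null(config$interaction_pair)) NULL else ids[config$interaction_pair],
    interaction_log_hr = config$interaction_log_hr,
    interaction_main_log_hrs = config$interaction_main_log_hrs,
    covariate_log_hrs = config$covariate_log_hrs,
    discovery_genes = ids,
    validation_genes = ids[keep_idx])
  list(discovery_genes = ids, validation_genes = ids[keep_idx], truth = truth)
}

#' Simulate one complete cohort (expression, clinical, survival)
#'
#' @param config a [sim_config()].
#' @return list with `fpkm`, `counts`, `clinical`, `survival`.
#' @export
simulate_cohort <- function(config) {
  clin <- simulate_covariates(config)
  expr <- simulate_expression(config)
  surv <- simulate_survival(expr$fpkm, clin, config)
  list(fpkm = expr$fpkm, counts = expr$counts, clinical = clin, survival = surv)
}

#' Simulate a linked discovery + validation two-phase study
#'
#' Generates two independent cohorts from the same ground-truth
#' configuration (the validation cohort with its own sub-seed and size) and
#' restricts the validation cohort to the partially overlapping platform.
#'
#' @param config a [sim_config()] describing the discovery cohort.
#' @param n_validation validation cohort size (default: same as discovery).
#' @param force_missing see [split_platforms()].
#' @return list with `discovery`, `validation` (each a cohort list) and
#'   `truth`.
#' @export
simulate_two_phase <- function(config, n_validation = config$n_subjects,
                               force_missing = FALSE) {
  disc <- simulate_cohort(config)
  vcfg <- config
  vcfg$n_subjects <- as.integer(n_validation)
  vcfg$seed <- as.integer(derive_seed(config$seed, "validation-cohort") %% 2147483646)
  val <- simulate_cohort(vcfg)
  val$clinical$sample_id <- sub("^S", "V", val$clinical$sample_id)
  val$survival$sample_id <- sub("^S", "V", val$survival$sample_id)
  colnames(val$fpkm) <- sub("^S", "V", colnames(val$fpkm))
  colnames(val$counts) <- sub("^S", "V", colnames(val$counts))
  sp <- split_platforms(disc$fpkm, config, force_missing = force_missing)
  vg <- sp$validation_genes
  val$fpkm <- expression_matrix(unclass(val$fpkm)[vg, , drop = FALSE], "fpkm")
  val$counts <- expression_matrix(unclass(val$counts)[vg, , drop = FALSE], "counts")
  list(discovery = disc, validation = val, truth = sp$truth)
}
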