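# Ground-truth generators for every pipeline stage: multi-cohort
# expression with planted differentially expressed genes and between-study
# heterogeneity, a perturbation compendium with a planted
# signature-reversing drug, gene-set collections with a planted enriched
# set, and survival cohorts with a known hazard ratio and confounding
# knobs. One run seed fans out to per-component child seeds by fixed
# offsets so components regenerate stably.

#' Simulation configuration for multi-cohort expression data
#'
#' @param n_datasets Number of cohorts.
#' @param per_group_sizes Two-column matrix/data.frame of per-cohort
#'   `(n_case, n_ctrl)`, each >= 2.
#' @param n_genes Genes per cohort before dropout.
#' @param n_de Planted differentially expressed genes (`<= n_genes`).
#' @param de_effect_mean Mean absolute planted effect, on the Hedges-g
#'   scale (within-group variance is 1).
#' @param tau2 Between-study variance of the true per-cohort effects
#'   (random-effects generating model).
#' @param platform_dropout Fraction of genes removed at random from each
#'   cohort's panel, in `[0, 1)`.
#' @param seed Integer run seed.
#' @return List of class `SimConfig`.
#' @export
sim_config <- function(n_datasets, per_group_sizes, n_genes, n_de,
                       de_effect_mean = 1.0, tau2 = 0, platform_dropout = 0,
                       seed = 1L) {
  per_group_sizes <- as.matrix(per_group_sizes)
  stopifnot(nrow(per_group_sizes) == n_datasets,
            all(per_group_sizes >= 2),
            n_de <= n_genes, tau2 >= 0,
            platform_dropout >= 0, platform_dropout < 1)
  structure(list(n_datasets = n_datasets,
                 per_group_sizes = per_group_sizes,
                 n_genes = n_genes, n_de = n_de,
                 de_effect_mean = de_effect_mean, tau2 = tau2,
                 platform_dropout = platform_dropout,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

#' Configuration mirroring the 11-cohort discovery setting
#'
#' Eleven cohorts with the per-study case/control sizes of the published
#' colon-biopsy compendium (272 samples), 10000 genes, 500 planted
#' differentially expressed genes at mean |g| = 1, and low between-study
#' heterogeneity (tau2 = 0.05).
#'
#' @param seed Run seed.
#' @param ... Overrides passed to [sim_config()].
#' @return A `SimConfig`.
#' @export
uc_study_config <- function(seed = 1L, ...) {
  sizes <- uc_cohort_sizes()[, c("n_case", "n_ctrl")]
  args <- list(n_datasets = nrow(sizes), per_group_sizes = sizes,
               n_genes = 10000L, n_de = 500L, de_effect_mean = 1.0,
               tau2 = 0.05, platform_dropout = 0, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

#' Generate a multi-cohort expression collection with planted truth
#'
#' For each cohort i and planted gene j, case samples are drawn
#' `Normal(delta_ij, 1)` and controls `Normal(0, 1)`, with the cohort-level
#' true effect `delta_ij ~ Normal(sign_j * de_effect_mean, tau2)`
#' (random-effects generating model). Non-planted genes are `Normal(0, 1)`
#' in both groups. A `platform_dropout` fraction of genes is removed from
#' each cohort's panel at random.
#'
#' @param config A [sim_config()].
#' @return List: `datasets` (list of `ExpressionDataset`) and `truth`
#'   (list with `de_genes` — named sign vector — and `true_effects`).
#' @export
gen_multicohort <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  genes <- sprintf("G%05d", seq_len(config$n_genes))
  set.seed(config$seed)
  de_idx <- if (config$n_de > 0)
    sort(sample.int(config$n_genes, config$n_de)) else integer(0)
  signs <- if (config$n_de > 0)
    sample(c(-1, 1), config$n_de, replace = TRUE) else numeric(0)
  true_eff <- stats::setNames(rep(0, config$n_genes), genes)
  true_eff[de_idx] <- signs * config$de_effect_mean
  datasets <- vector("list", config$n_datasets)
  for (i in seq_len(config$n_datasets)) {
    set.seed(config$seed + 1000L * i)   # fixed child-seed offset
    n1 <- config$per_group_sizes[i, 1]; n2 <- config$per_group_sizes[i, 2]
    delta <- rep(0, config$n_genes)
    if (config$n_de > 0)
      delta[de_idx] <- stats::rnorm(config$n_de,
                                    signs * config$de_effect_mean,
                                    sqrt(config$tau2))
    expr <- matrix(stats::rnorm(config$n_genes * (n1 + n2)),
                   config$n_genes, n1 + n2)
    expr[, seq_len(n1)] <- expr[, seq_len(n1)] + delta
    rownames(expr) <- genes
    colnames(expr) <- sprintf("DS%02d_S%03d", i, seq_len(n1 + n2))
    labels <- c(rep("case", n1), rep("control", n2))
    if (config$platform_dropout > 0) {
      drop_n <- floor(config$platform_dropout * config$n_genes)
      keep <- sort(sample.int(config$n_genes, config$n_genes - drop_n))
      expr <- expr[keep, , drop = FALSE]
    }
    datasets[[i]] <- expression_dataset(sprintf("SIM%02d", i), expr, labels,
                                        platform = "simulated")
  }
  list(datasets = datasets,
       truth = list(de_genes = stats::setNames(signs, genes[de_idx]),
                    true_effects = true_eff))
}

#' Generate a drug-perturbation compendium with a planted reverser
#'
#' One designated drug (`reverser`) has per-gene effects
#' `-disease_es + Normal(0, noise_sd)`; one (`mimic`) has
#' `+disease_es + noise`; the remaining drugs are `Normal(0, 1)` i.i.d.
#' A random `gold_fraction` of genes is flagged reliable ("gold").
#'
#' @param disease_es Named numeric vector of disease effect sizes (the
#'   gene universe of the compendium).
#' @param n_drugs Total drugs including reverser and mimic (`>= 2`).
#' @param noise_sd Noise standard deviation on the planted profiles.
#' @param seed Seed.
#' @param gold_fraction Fraction of genes flagged gold (default 0.6).
#' @return List: `compendium` (a `DrugCompendium`) and `truth` (list with
#'   `reverser_drug`, `mimic_drug`).
#' @export
gen_drug_compendium <- function(disease_es, n_drugs, noise_sd = 1,
                                seed = 1L, gold_fraction = 0.6) {
  stopifnot(length(disease_es) > 0, n_drugs >= 2)
  set.seed(seed)
  genes <- names(disease_es)
  n_null <- n_drugs - 2L
  eff <- matrix(stats::rnorm(length(genes) * n_null),
                length(genes), n_null,
                dimnames = list(genes, sprintf("drug_%04d", seq_len(n_null))))
  reverser <- -disease_es + stats::rnorm(length(genes), 0, noise_sd)
  mimic <- disease_es + stats::rnorm(length(genes), 0, noise_sd)
  eff <- cbind(eff, reverser = reverser, mimic = mimic)
  gold <- stats::setNames(rep(FALSE, length(genes)), genes)
  gold[sample.int(length(genes), round(gold_fraction * length(genes)))] <- TRUE
  list(compendium = drug_compendium(eff, gold),
       truth = list(reverser_drug = "reverser", mimic_drug = "mimic"))
}

#' Generate a gene-set collection with one planted enriched set
#'
#' The planted set draws `planted_fraction` of its members from
#' `signature`, the rest (and all other sets) uniformly from the universe.
#' Set sizes are uniform over `set_size_range`.
#'
#' @param universe Character vector of genes.
#' @param n_sets Number of sets.
#' @param set_size_range Length-2 integer range of set sizes.
#' @param planted_fraction Fraction of the planted set drawn from
#'   `signature`.
#' @param signature Character vector of signature genes.
#' @param seed Seed.
#' @return List: `collection` (named list, planted set named `"planted"`)
#'   and `truth` (list with `enriched_set`).
#' @export
gen_gene_sets <- function(universe, n_sets, set_size_range,
                          planted_fraction, signature, seed = 1L) {
  stopifnot(max(set_size_range) <= length(universe),
            planted_fraction >= 0, planted_fraction <= 1)
  set.seed(seed)
  size_rng <- seq.int(set_size_range[1], set_size_range[2])
  sizes <- size_rng[sample.int(length(size_rng), n_sets, replace = TRUE)]
  collection <- vector("list", n_sets)
  names(collection) <- c("planted",
                         if (n_sets > 1) sprintf("set_%03d", seq_len(n_sets - 1L)))
  for (i in seq_len(n_sets)) {
    if (i == 1L) {
      n_sig <- min(round(planted_fraction * sizes[i]), length(signature))
      from_sig <- sample(signature, n_sig)
      from_uni <- sample(setdiff(universe, from_sig), sizes[i] - n_sig)
      collection[[i]] <- unique(c(from_sig, from_uni))
    } else {
      collection[[i]] <- sample(universe, sizes[i])
    }
  }
  list(collection = collection, truth = list(enriched_set = "planted"))
}

#' Generate a survival cohort with a known treatment hazard ratio
#'
#' Covariates: age `Normal(58, 15)` truncated at 18, sex `Bernoulli(0.5)`,
#' and `n_comorbidities` binary comorbidities `Bernoulli(0.3)`. Exposure is
#' assigned by a logistic model whose intercept is calibrated so the
#' marginal treatment rate is approximately `exposure_prob`. Event times
#' are exponential with hazard
#' `h0 * exp(log(true_hr) * exposure + covariate effects)`, so proportional
#' hazards hold by construction; independent exponential censoring is tuned
#' to the requested censoring fraction. A control outcome (hazard affected
#' by the confounders but not by treatment) and an exposure-independent
#' prescription duration are emitted for the negative-control and
#' duration-sensitivity analyses.
#'
#' @param n Subjects.
#' @param true_hr Treatment hazard ratio (> 0) on the primary outcome.
#' @param exposure_prob Target marginal exposure rate in (0, 1).
#' @param confounders `NULL`, or a list with named numeric vectors
#'   `exposure` and `hazard` giving log-odds / log-hazard effects of
#'   covariates (`age_std`, `sex`, `comorbidity_1`, ...) on treatment
#'   assignment and on both outcomes (the healthy-user analog).
#' @param censor_rate Target fraction censored, in `[0, 1)`.
#' @param seed Seed.
#' @param n_comorbidities Number of binary comorbidity covariates.
#' @param baseline_hazard Events per day at covariate zero (default
#'   1/2000).
#' @param rx_duration_mean Mean prescription duration in days
#'   (exponential, independent of outcome).
#' @return List: `cohort` (a `CohortTable` data frame with columns
#'   `subject_id`, `exposure`, `index_date`, `age`, `age_std`, `sex`,
#'   `comorbidity_*`, `time_days`, `event`, `control_time_days`,
#'   `control_event`, `rx_duration_days`) and `truth` (list with
#'   `true_hr`).
#' @export
gen_survival_cohort <- function(n, true_hr, exposure_prob = 0.3,
                                confounders = NULL, censor_rate = 0.3,
                                seed = 1L, n_comorbidities = 3L,
                                baseline_hazard = 1 / 2000,
                                rx_duration_mean = 540) {
  stopifnot(true_hr > 0, exposure_prob > 0, exposure_prob < 1,
            censor_rate >= 0, censor_rate < 1)
  set.seed(seed)
  age <- pmax(stats::rnorm(n, 58, 15), 18)
  age_std <- (age - 58) / 15
  sex <- stats::rbinom(n, 1, 0.5)
  com <- matrix(stats::rbinom(n * n_comorbidities, 1, 0.3),
                n, n_comorbidities,
                dimnames = list(NULL, paste0("comorbidity_",
                                             seq_len(n_comorbidities))))
  covs <- cbind(age_std = age_std, sex = sex, com)
  lp_of <- function(coefs) {
    if (is.null(coefs)) return(rep(0, n))
    miss <- setdiff(names(coefs), colnames(covs))
    if (length(miss)) stop("unknown covariate(s): ",
                           paste(miss, collapse = ", "))
    drop(covs[, names(coefs), drop = FALSE] %*% coefs)
  }
  lp_expo <- lp_of(confounders$exposure)
  b0 <- stats::uniroot(function(b) mean(stats::plogis(b + lp_expo)) -
                         exposure_prob, c(-20, 20))$root
  exposure <- stats::rbinom(n, 1, stats::plogis(b0 + lp_expo))
  lp_haz <- lp_of(confounders$hazard)
  lambda <- baseline_hazard * exp(log(true_hr) * exposure + lp_haz)
  T_evt <- stats::rexp(n, lambda)
  if (censor_rate > 0) {
    mu <- stats::uniroot(function(m) mean(m / (m + lambda)) - censor_rate,
                         c(1e-12, 1e3), tol = 1e-12)$root
    C <- stats::rexp(n, mu)
  } else C <- rep(Inf, n)
  # control outcome: same confounder effects, no treatment effect
  lambda_c <- baseline_hazard * exp(lp_haz)
  T_ctl <- stats::rexp(n, lambda_c)
  cohort <- data.frame(
    subject_id = sprintf("S%06d", seq_len(n)),
    exposure = ifelse(exposure == 1, "treatment", "comparator"),
    index_date = sample.int(365L, n, replace = TRUE),
    age = age, age_std = age_std, sex = sex, com,
    time_days = pmin(T_evt, C), event = T_evt <= C,
    control_time_days = pmin(T_ctl, C), control_event = T_ctl <= C,
    rx_duration_days = stats::rexp(n, 1 / rx_duration_mean),
    stringsAsFactors = FALSE)
  class(cohort) <- c("CohortTable", "data.frame")
  list(cohort = cohort, truth = list(true_hr = true_hr))
}
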