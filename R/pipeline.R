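#' Run the full analysis pipeline on simulated or supplied data
#'
#' Orchestrates simulate (or ingest) -> normalize -> convergence testing
#' -> clock construction and age acceleration -> trajectory analysis ->
#' enrichment -> mortality, writing each stage's tables as TSV plus a
#' machine-readable JSON report. Day-9 A-type samples are excluded from
#' clock fitting and the mixed models (configurable via `exclude`), but
#' retained in the group-mean matrix for clustering.
#'
#' @param config a [sim_config()] describing the synthetic input, or a
#'   raw [abundance_table()] to analyse directly.
#' @param out_dir output directory (created if needed); `NULL` disables
#'   file output.
#' @param seed master seed; each stage derives its own seed from it and
#'   the report records all of them.
#' @param exclude list of `c(regime, age)` pairs dropped from clock and
#'   LMM inputs; default drops the day-9 A-type samples.
#' @param folds CV folds for discriminator and clocks.
#' @param fdr_lmm per-term BH threshold for the metabolite mixed models.
#' @param fdr_enrich FDR threshold for pathway enrichment.
#' @param k_max,n_init elbow-search bounds for the cluster count.
#' @param n_perm permutations for enrichment.
#' @param alpha_grid,nlambda elastic-net tuning-grid density.
#' @param mortality_params `regime -> c(baseline, growth)` hazards for the
#'   simulated mortality stage (used only when `config` is a
#'   `sim_config`).
#' @return the report as a named list (invisibly written to
#'   `out_dir/report.json` when `out_dir` is given).
#' @export
run_all <- function(config, out_dir = NULL, seed = 1,
                    exclude = list(c("A", 9)), folds = 5, fdr_lmm = 0.01,
                    fdr_enrich = 0.05, k_max = 30, n_init = 25,
                    n_perm = 2000, alpha_grid = seq(0.2, 1, by = 0.2),
                    nlambda = 60,
                    mortality_params = list(A = c(0.002, 0.12),
                                            C = c(0.002, 0.05))) {
  seeds <- list(simulate = seed, discriminator = seed + 1,
                clocks = seed + 2, elbow = seed + 3,
                enrichment = seed + 4, mortality = seed + 5)
  report <- list(seeds = seeds)

  if (inherits(config, "sim_config")) {
    sim <- simulate_metabolome(config, seed = seeds$simulate)
    raw <- sim$table
    network <- simulate_network(
      n_pathways = 5, metabolites_per_pathway = 8,
      n_background = max(0, config$n_metabolites - 40),
      seed = seeds$enrichment, metabolite_names = sim$truth$metabolite)
    deaths <- simulate_mortality(mortality_params, cohort_size = 1000,
                                 seed = seeds$mortality)
  } else if (inherits(config, "abundance_table")) {
    raw <- config
    network <- NULL
    deaths <- NULL
  } else {
    stop("config must be a sim_config or an abundance_table")
  }

  norm <- normalize_abundance(raw)
  keep <- rep(TRUE, nrow(norm$values))
  for (ex in exclude) {
    keep <- keep & !(norm$meta$regime == ex[1] &
                     norm$meta$age_days == as.numeric(ex[2]))
  }
  analysis <- subset_samples(norm, keep)

  # Objective 1: convergence
  common_ages <- Reduce(intersect,
                        lapply(split(norm$meta$age_days, norm$meta$regime),
                               unique))
  pcs <- pca_covariance(norm, ages = common_ages)
  divergence <- test_pc_divergence(pcs)
  long <- subset_samples(norm, norm$meta$history == "long")
  disc <- train_regime_discriminator(long, ages = common_ages,
                                     folds = folds,
                                     seed = seeds$discriminator)
  recent <- subset_samples(norm, norm$meta$history == "recent" &
                             norm$meta$age_days %in% common_ages)
  transfer <- predict(disc, recent)

  report$convergence <- list(
    divergence_declared = divergence$divergence,
    pc_variance_first4 = sum(pcs$var_explained[1:4]),
    discriminator_train_accuracy = disc$train_accuracy,
    discriminator_cv_accuracy = disc$cv_accuracy,
    discriminator_auc = disc$auc,
    transfer_accuracy = transfer$accuracy)

  # Objective 2: clocks and age acceleration
  a_tab <- subset_samples(analysis, analysis$meta$regime == "A")
  c_tab <- subset_samples(analysis, analysis$meta$regime == "C")
  within_a <- loro_predictions(a_tab, folds = folds, seed = seeds$clocks,
                               alpha_grid = alpha_grid, nlambda = nlambda)
  within_c <- loro_predictions(c_tab, folds = folds,
                               seed = seeds$clocks + 100,
                               alpha_grid = alpha_grid, nlambda = nlambda)
  between_on_a <- between_regime_predictions(c_tab, a_tab, folds = folds,
                                             seed = seeds$clocks + 200,
                                             alpha_grid = alpha_grid,
                                             nlambda = nlambda)
  between_on_c <- between_regime_predictions(a_tab, c_tab, folds = folds,
                                             seed = seeds$clocks + 300,
                                             alpha_grid = alpha_grid,
                                             nlambda = nlambda)
  acc_c_clock <- fit_age_acceleration(within_c,
                                      between_on_a$predictions)
  acc_a_clock <- fit_age_acceleration(within_a,
                                      between_on_c$predictions)
  fc <- compare_features(between_on_c$clock, between_on_a$clock,
                         panel_size = ncol(analysis$values))
  report$clocks <- list(
    r2_within_a = r_squared(within_a$age_days, within_a$predicted),
    r2_within_c = r_squared(within_c$age_days, within_c$predicted),
    c_clock_acceleration = list(
      coefficients = as.list(coef(acc_c_clock)),
      p_values = as.list(acc_c_clock$table[, 4])),
    a_clock_acceleration = list(
      coefficients = as.list(coef(acc_a_clock)),
      p_values = as.list(acc_a_clock$table[, 4])),
    features_a = fc$n_a, features_c = fc$n_c, features_shared = fc$n_shared,
    feature_odds_ratio = fc$odds_ratio, feature_fisher_p = fc$fisher_p)

  # Objective 3: trajectories
  lmm <- fit_metabolite_lmms(analysis, fdr = fdr_lmm)
  counts <- term_overlap_counts(lmm)
  gm <- group_means(norm)
  elbow <- choose_k_elbow(gm, k_max = min(k_max, nrow(gm) - 1),
                          n_init = n_init, seed = seeds$elbow)
  K <- max(2, elbow$K)
  clusters <- hierarchical_cluster(gm, K = K)
  flags <- tryCatch(flag_aged_phenotype(clusters, gm),
                    error = function(e) NULL)
  report$trajectories <- list(
    n_significant = counts$total_significant,
    per_term = as.list(counts$per_term),
    subsets = as.list(counts$subsets),
    chosen_K = elbow$K,
    aged_phenotype_clusters = if (is.null(flags)) NULL else
      as.integer(names(flags)[flags]))

  # Enrichment per aged-phenotype cluster (synthetic network only)
  enrich <- NULL
  if (!is.null(network)) {
    enrich <- list()
    for (k in sort(unique(clusters$assignments))) {
      mets <- names(clusters$assignments)[clusters$assignments == k]
      res <- suppressMessages(permutation_enrichment(
        network, mets, n_perm = n_perm, fdr = fdr_enrich,
        seed = seeds$enrichment + k))
      if (!is.null(res)) {
        enrich[[as.character(k)]] <-
          res[res$significant, c("pathway", "score", "p_score", "fdr")]
      }
    }
    report$enrichment <- list(
      clusters_tested = length(enrich),
      significant_pathways = sum(vapply(enrich, nrow, 1L)))
  }

  # Mortality summary
  if (!is.null(deaths)) {
    med <- vapply(split(deaths, deaths$regime), function(d) {
      pooled <- pool_cohorts(split(d, d$cohort))
      ms <- age_specific_mortality(pooled)
      surv <- cumsum(ms$deaths)
      ms$day[which(surv >= sum(ms$deaths) / 2)[1]]
    }, 1)
    report$mortality <- list(median_death_day = as.list(med))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_abundance(norm, file.path(out_dir, "normalized.tsv"))
    utils::write.table(as.data.frame(rbind(within_a, within_c,
                                           between_on_a$predictions,
                                           between_on_c$predictions)),
                       file.path(out_dir, "age_predictions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(lmm),
                       file.path(out_dir, "lmm_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(metabolite = names(clusters$assignments),
                 cluster = clusters$assignments),
      file.path(out_dir, "clusters.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(report)
}
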