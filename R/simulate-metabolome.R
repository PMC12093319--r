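#' Simulation configuration for the study design
#'
#' Describes the factorial design being emulated: two selection regimes
#' (A = accelerated, 10-day generation cycle; C = control, 28-day cycle),
#' two selection histories per regime (long-standing and recently derived),
#' five replicate populations per regime-by-history cell, one pooled sample
#' per population at each of that regime's sampling ages, and LC-MS batch
#' structure. Defaults reproduce the study layout: A-type populations
#' sampled at 9, 21, 28 and 35 days from egg, C-type at 21, 28, 35 and 70,
#' giving 80 pooled samples over 202 metabolites in 3 batches.
#'
#' Latent log-abundance of metabolite m in sample s is
#' `baseline_m + [age-responsive] slope_regime * age + [regime-responsive]
#' offset * I(A) + [interaction] extra_slope * I(A) * age +
#' history_effect * I(recent) + replicate intercept + batch effect +
#' residual`, and the emitted value is the exponential of that latent
#' signal, so the downstream log-transform is meaningful. Day-9 A-type
#' samples additionally receive a post-eclosion offset on a random 30% of
#' metabolites, mimicking the transient physiological state of newly
#' eclosed flies.
#'
#' @param n_metabolites number of metabolites in the panel.
#' @param n_replicates_per_population replicate populations per
#'   regime-by-history cell.
#' @param regimes,histories factor labels; the defaults are the study's.
#' @param ages_by_regime named list mapping each regime to its strictly
#'   increasing vector of sampling ages (days from egg).
#' @param n_batches number of LC-MS batches samples are spread over.
#' @param latent_aging_slope named vector, log-abundance units per day, one
#'   entry per regime, applied to age-responsive metabolites.
#' @param regime_offset log-abundance offset added to regime-responsive
#'   metabolites in A-type samples.
#' @param interaction_slope extra per-day slope added to interaction
#'   metabolites in A-type samples.
#' @param history_effect_size log-abundance offset added to recently
#'   derived samples (0 = histories have converged, the study's finding).
#' @param batch_sd,replicate_sd,residual_sd standard deviations of the
#'   batch, replicate-population, and residual Gaussian effects
#'   (log-abundance units). Residual noise is small because each sample
#'   pools ~50 flies.
#' @param frac_age_responsive,frac_regime_responsive,frac_interaction
#'   proportions of metabolites carrying each effect.
#' @param eclosion_offset_sd log-abundance SD of the day-9 post-eclosion
#'   offset (A-type only; applied to a random 30% of metabolites).
#' @param frac_missing proportion of metabolites rendered incomplete
#'   (missing in a random sample) to exercise the completeness filter.
#' @param n_pooled nominal number of flies pooled per sample.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_metabolites = 202,
                       n_replicates_per_population = 5,
                       regimes = c("A", "C"),
                       histories = c("long", "recent"),
                       ages_by_regime = list(A = c(9, 21, 28, 35),
                                             C = c(21, 28, 35, 70)),
                       n_batches = 3,
                       latent_aging_slope = c(A = 0.04, C = 0.02),
                       regime_offset = 0.5,
                       interaction_slope = 0,
                       history_effect_size = 0,
                       batch_sd = 0.2,
                       replicate_sd = 0.05,
                       residual_sd = 0.1,
                       frac_age_responsive = 0.5,
                       frac_regime_responsive = 0.2,
                       frac_interaction = 0,
                       eclosion_offset_sd = 1,
                       frac_missing = 0,
                       n_pooled = 50) {
  cfg <- list(n_metabolites = n_metabolites,
              n_replicates_per_population = n_replicates_per_population,
              regimes = regimes, histories = histories,
              ages_by_regime = ages_by_regime, n_batches = n_batches,
              latent_aging_slope = latent_aging_slope,
              regime_offset = regime_offset,
              interaction_slope = interaction_slope,
              history_effect_size = history_effect_size,
              batch_sd = batch_sd, replicate_sd = replicate_sd,
              residual_sd = residual_sd,
              frac_age_responsive = frac_age_responsive,
              frac_regime_responsive = frac_regime_responsive,
              frac_interaction = frac_interaction,
              eclosion_offset_sd = eclosion_offset_sd,
              frac_missing = frac_missing,
              n_pooled = n_pooled)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  sds <- c(cfg$batch_sd, cfg$replicate_sd, cfg$residual_sd,
           cfg$eclosion_offset_sd)
  if (any(sds < 0)) stop("all standard deviations must be >= 0")
  fr <- c(cfg$frac_age_responsive, cfg$frac_regime_responsive,
          cfg$frac_interaction, cfg$frac_missing)
  if (any(fr < 0 | fr > 1)) stop("all fractions must lie in [0, 1]")
  if (cfg$n_metabolites < 1 || cfg$n_replicates_per_population < 1 ||
      cfg$n_batches < 1) stop("counts must be >= 1")
  for (rg in cfg$regimes) {
    ages <- cfg$ages_by_regime[[rg]]
    if (is.null(ages)) stop("no ages given for regime ", rg)
    if (length(ages) < 2) {
      stop("regime ", rg, " has fewer than 2 sampling ages; ",
           "age-clock fitting is impossible")
    }
    if (any(diff(ages) <= 0)) {
      stop("ages for regime ", rg, " must be strictly increasing")
    }
  }
  if (!all(cfg$regimes %in% names(cfg$latent_aging_slope))) {
    stop("latent_aging_slope must name every regime")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  n_samp <- sum(vapply(x$regimes, function(rg)
    length(x$ages_by_regime[[rg]]), 1L)) *
    length(x$histories) * x$n_replicates_per_population
  cat("<sim_config> ", x$n_metabolites, " metabolites, ", n_samp,
      " samples (", length(x$regimes), " regimes x ", length(x$histories),
      " histories x ", x$n_replicates_per_population, " replicates), ",
      x$n_batches, " batches\n", sep = "")
  invisible(x)
}

#' Simulate a pooled-sample metabolome under the study design
#'
#' Generates one pooled sample per (replicate population, sampling age) on
#' a positive abundance scale, together with the ground truth of which
#' metabolites carry which effects, so downstream inference can be scored
#' against the generative process.
#'
#' @param config a [sim_config()].
#' @param seed integer; fully determines the output.
#' @return a list with elements `table` (a raw [abundance_table()]) and
#'   `truth` (data frame with one row per metabolite: logical columns
#'   `age_responsive`, `regime_responsive`, `interaction`, plus the
#'   per-metabolite baseline), and `slopes` (the per-regime latent aging
#'   slopes used).
#' @export
simulate_metabolome <- function(config, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(seed)
  nm <- config$n_metabolites
  mets <- sprintf("met_%03d", seq_len(nm))

  truth <- data.frame(
    metabolite = mets,
    baseline = stats::rnorm(nm, mean = 10, sd = 1),
    age_responsive = stats::runif(nm) < config$frac_age_responsive,
    regime_responsive = stats::runif(nm) < config$frac_regime_responsive,
    interaction = stats::runif(nm) < config$frac_interaction,
    stringsAsFactors = FALSE)

  # design: one row per (regime, history, replicate, age)
  rows <- list()
  for (rg in config$regimes) {
    for (hs in config$histories) {
      for (rp in seq_len(config$n_replicates_per_population)) {
        for (ag in config$ages_by_regime[[rg]]) {
          rows[[length(rows) + 1]] <- data.frame(
            regime = rg, history = hs,
            replicate = paste(rg, hs, rp, sep = "_"),
            age_days = ag, stringsAsFactors = FALSE)
        }
      }
    }
  }
  meta <- do.call(rbind, rows)
  ns <- nrow(meta)
  meta$sample_id <- sprintf("s%03d_%s_%d", seq_len(ns), meta$regime,
                            meta$age_days)
  # random batch assignment: batches are processing days, unconfounded
  # with the design by randomization
  meta$batch <- sample(rep_len(seq_len(config$n_batches), ns))
  meta$n_pooled <- config$n_pooled
  meta <- meta[c("sample_id", "regime", "history", "replicate", "age_days",
                 "batch", "n_pooled")]

  reps <- unique(meta$replicate)
  rep_int <- stats::rnorm(length(reps), 0, config$replicate_sd)
  names(rep_int) <- reps
  batch_eff <- matrix(stats::rnorm(config$n_batches * nm, 0,
                                   config$batch_sd),
                      nrow = config$n_batches)

  is_a <- meta$regime == "A"
  is_recent <- meta$history == "recent"
  slope <- config$latent_aging_slope[meta$regime]

  latent <- matrix(rep(truth$baseline, each = ns), nrow = ns)
  age <- meta$age_days
  for (j in seq_len(nm)) {
    mu <- latent[, j]
    if (truth$age_responsive[j]) mu <- mu + slope * age
    if (truth$regime_responsive[j]) mu <- mu + config$regime_offset * is_a
    if (truth$interaction[j]) {
      mu <- mu + config$interaction_slope * is_a * age
    }
    latent[, j] <- mu
  }
  latent <- latent + config$history_effect_size * is_recent +
    rep_int[meta$replicate] + batch_eff[meta$batch, , drop = FALSE] +
    matrix(stats::rnorm(ns * nm, 0, config$residual_sd), nrow = ns)

  # transient post-eclosion signature on day-9 A-type samples
  day9 <- is_a & meta$age_days == 9
  if (any(day9) && config$eclosion_offset_sd > 0) {
    affected <- sample(nm, size = round(0.3 * nm))
    offs <- stats::rnorm(length(affected), 0, config$eclosion_offset_sd)
    latent[day9, affected] <- sweep(latent[day9, affected, drop = FALSE],
                                    2, offs, `+`)
  }

  values <- exp(latent)
  colnames(values) <- mets
  rownames(values) <- meta$sample_id

  if (config$frac_missing > 0) {
    incomplete <- which(stats::runif(nm) < config$frac_missing)
    for (j in incomplete) values[sample(ns, 1), j] <- NA_real_
    truth$complete <- !seq_len(nm) %in% incomplete
  } else {
    truth$complete <- TRUE
  }

  list(table = abundance_table(values, meta, stage = "raw"),
       truth = truth,
       slopes = config$latent_aging_slope)
}
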