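#' Leave-one-replicate-out age predictions within a regime
#'
#' For each replicate population in turn, fits a clock on every other
#' replicate's samples and predicts the ages of the withheld replicate, so
#' that no prediction comes from a model whose training data contained any
#' sample of the predicted sample's biological replicate. Each iteration's
#' CV folds are seeded as `seed + replicate index` for reproducibility.
#'
#' @param regime_table a normalized [abundance_table()] holding one
#'   regime's samples (day-9 A-type samples excluded upstream); needs
#'   `replicate` and `age_days` metadata and >= 3 replicate populations.
#' @param folds,seed,alpha_grid,nlambda,lambda_min_ratio passed to
#'   [fit_clock()].
#' @return an object of class `age_prediction_set`: data frame with
#'   columns `sample_id`, `replicate`, `age_days`, `predicted`, `mode`
#'   (`"within"`), `sample_regime`, `clock_regime`; attributes
#'   `leakage_free = TRUE` and `training_index` (per-replicate list of
#'   training sample ids, for structural leakage audits).
#' @export
loro_predictions <- function(regime_table, folds = 5, seed = 1,
                             alpha_grid = seq(0.1, 1, by = 0.1),
                             nlambda = 100, lambda_min_ratio = 1e-4) {
  stopifnot(inherits(regime_table, "abundance_table"))
  meta <- regime_table$meta
  reps <- sort(unique(meta$replicate))
  if (length(reps) < 3) stop("need >= 3 replicate populations for LORO")
  ages <- sort(unique(meta$age_days))
  for (r in reps) {
    left <- unique(meta$age_days[meta$replicate != r])
    if (!all(ages %in% left)) {
      stop("withholding replicate ", r, " would remove age level(s) ",
           paste(setdiff(ages, left), collapse = ", "),
           " from the training data")
    }
  }
  out <- vector("list", length(reps))
  training_index <- list()
  rg <- unique(meta$regime)
  rg <- if (length(rg) == 1) rg else NA_character_
  for (i in seq_along(reps)) {
    r <- reps[i]
    hold <- meta$replicate == r
    train <- subset_samples(regime_table, !hold)
    clock <- fit_clock(train, folds = folds, seed = seed + i,
                       alpha_grid = alpha_grid, nlambda = nlambda,
                       lambda_min_ratio = lambda_min_ratio, regime = rg)
    test <- subset_samples(regime_table, hold)
    out[[i]] <- data.frame(sample_id = test$meta$sample_id,
                           replicate = r,
                           age_days = test$meta$age_days,
                           predicted = predict(clock, test),
                           mode = "within",
                           sample_regime = test$meta$regime,
                           clock_regime = rg,
                           stringsAsFactors = FALSE)
    training_index[[r]] <- train$meta$sample_id
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "leakage_free") <- TRUE
  attr(res, "training_index") <- training_index
  class(res) <- c("age_prediction_set", "data.frame")
  res
}

#' Between-regime age predictions
#'
#' Fits a clock on *all* samples of the clock regime and predicts the ages
#' of the opposite regime's samples only, so predictions are again made on
#' data absent from training.
#'
#' @param clock_regime_table normalized [abundance_table()] of the regime
#'   the clock is trained on.
#' @param target_regime_table normalized [abundance_table()] of the
#'   opposite regime (same metabolite columns).
#' @param folds,seed,alpha_grid,nlambda,lambda_min_ratio passed to
#'   [fit_clock()].
#' @return a list with `clock` (the fitted [fit_clock()] model) and
#'   `predictions` (an `age_prediction_set` with mode `"between"`).
#' @export
between_regime_predictions <- function(clock_regime_table,
                                       target_regime_table, folds = 5,
                                       seed = 1,
                                       alpha_grid = seq(0.1, 1, by = 0.1),
                                       nlambda = 100,
                                       lambda_min_ratio = 1e-4) {
  stopifnot(inherits(clock_regime_table, "abundance_table"),
            inherits(target_regime_table, "abundance_table"))
  rg_clock <- unique(clock_regime_table$meta$regime)
  rg_target <- unique(target_regime_table$meta$regime)
  if (length(intersect(rg_clock, rg_target)) > 0) {
    stop("clock and target tables share regime(s) ",
         paste(intersect(rg_clock, rg_target), collapse = ", "),
         "; between-regime prediction requires disjoint regimes")
  }
  if (!setequal(colnames(clock_regime_table$values),
                colnames(target_regime_table$values))) {
    stop("metabolite columns differ between the two tables")
  }
  clock <- fit_clock(clock_regime_table, folds = folds, seed = seed,
                     alpha_grid = alpha_grid, nlambda = nlambda,
                     lambda_min_ratio = lambda_min_ratio,
                     regime = paste(rg_clock, collapse = "+"))
  tm <- target_regime_table$meta
  res <- data.frame(sample_id = tm$sample_id, replicate = tm$replicate,
                    age_days = tm$age_days,
                    predicted = predict(clock, target_regime_table),
                    mode = "between", sample_regime = tm$regime,
                    clock_regime = clock$regime,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "leakage_free") <- TRUE
  class(res) <- c("age_prediction_set", "data.frame")
  list(clock = clock, predictions = res)
}

#' @export
print.age_prediction_set <- function(x, ...) {
  r2 <- if (stats::var(x$age_days) > 0)
    round(r_squared(x$age_days, x$predicted), 3) else NA
  cat("<age_prediction_set> ", nrow(x), " predictions (mode: ",
      paste(unique(x$mode), collapse = "/"), "); R^2 = ", r2, "\n",
      sep = "")
  invisible(x)
}
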