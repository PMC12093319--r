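make_age_table <- function(n_reps = 5, ages = c(21, 28, 35, 70), nm = 50,
                           n_causal = 5, noise = 0.01, slope = 0.1,
                           seed = 1, regime = "C") {
  set.seed(seed)
  meta <- expand.grid(replicate = sprintf("r%02d", seq_len(n_reps)),
                      age_days = ages, stringsAsFactors = FALSE)
  n <- nrow(meta)
  meta$sample_id <- sprintf("s%03d", seq_len(n))
  meta$regime <- regime
  meta$history <- "long"
  meta$batch <- 1
  meta$n_pooled <- 50
  x <- matrix(stats::rnorm(n * nm, sd = 1), n, nm)
  colnames(x) <- sprintf("m%03d", seq_len(nm))
  for (j in seq_len(n_causal)) {
    x[, j] <- slope * meta$age_days + stats::rnorm(n, sd = noise)
  }
  abundance_table(x, meta, stage = "normalized")
}

test_that("clock recovers a noise-free age signal", {
  tab <- make_age_table(noise = 1e-4, seed = 2)
  clock <- fit_clock(tab, seed = 1, alpha_grid = c(0.5, 1), nlambda = 50)
  pred <- predict(clock, tab)
  expect_gt(r_squared(tab$meta$age_days, pred), 0.99)
  # causal metabolites dominate the selected features
  causal <- sprintf("m%03d", 1:5)
  expect_gt(length(intersect(clock$features, causal)), 0)
  expect_lte(length(setdiff(clock$features, causal)), 10)
  expect_setequal(clock$features, names(clock$beta)[clock$beta != 0])
})

test_that("degenerate clock inputs are rejected", {
  tab <- make_age_table(ages = 28)
  expect_error(fit_clock(tab), "zero variance")
})

test_that("the infinite-penalty limit predicts the mean training age", {
  tab <- make_age_table(seed = 3)
  null_clock <- metaboclock:::new_metabolomic_clock(
    beta = stats::setNames(numeric(ncol(tab$values)),
                           colnames(tab$values)),
    intercept = mean(tab$meta$age_days),
    center = colMeans(tab$values),
    scale = apply(tab$values, 2, stats::sd),
    alpha = 1, lambda = Inf)
  expect_equal(unname(predict(null_clock, tab)),
               rep(mean(tab$meta$age_days), nrow(tab$values)))
  expect_length(null_clock$features, 0)
})

test_that("r_squared follows the printed formula exactly", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  y <- c(4, 8, 15, 16, 23)
  expect_equal(r_squared(y, rep(mean(y), 5)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  # brute-force oracle on random vectors
  set.seed(9)
  for (i in 1:20) {
    y <- stats::rnorm(10); yh <- stats::rnorm(10)
    oracle <- 1 - sum((y - yh)^2) / sum((y - mean(y))^2)
    expect_equal(r_squared(y, yh), oracle, tolerance = 1e-12)
  }
  expect_error(r_squared(c(1, 1), c(1, 2)), "constant")
  expect_error(r_squared(1:3, 1:4), "length")
})

test_that("LORO withholds whole replicates and covers each sample once", {
  # C-type study design: 10 replicates x 4 ages -> 36 training samples
  # per iteration
  norm <- shared_norm$norm
  c_tab <- subset_samples(norm, norm$meta$regime == "C")
  preds <- loro_predictions(c_tab, seed = 1, alpha_grid = c(0.5, 1),
                            nlambda = 30)
  expect_setequal(preds$sample_id, c_tab$meta$sample_id)
  expect_equal(nrow(preds), 40)
  ti <- attr(preds, "training_index")
  expect_true(attr(preds, "leakage_free"))
  for (r in names(ti)) {
    expect_length(ti[[r]], 36)
    # structural leakage audit: no training sample shares the withheld
    # replicate
    train_reps <- c_tab$meta$replicate[match(ti[[r]], c_tab$meta$sample_id)]
    expect_false(r %in% train_reps)
  }
  # permutation invariance over input row order
  shuf <- sample(nrow(c_tab$values))
  preds2 <- loro_predictions(subset_samples(c_tab, shuf), seed = 1,
                             alpha_grid = c(0.5, 1), nlambda = 30)
  m <- match(preds$sample_id, preds2$sample_id)
  expect_equal(preds$predicted, preds2$predicted[m], tolerance = 1e-10)
  # accuracy on low-noise synthetic data
  expect_gt(r_squared(preds$age_days, preds$predicted), 0.8)
})

test_that("LORO refuses designs where a replicate owns an age level", {
  tab <- make_age_table(n_reps = 4, ages = c(21, 28, 35))
  drop <- !(tab$meta$age_days == 35 & tab$meta$replicate != "r01")
  crippled <- subset_samples(tab, drop)
  expect_error(loro_predictions(crippled, alpha_grid = 1, nlambda = 20),
               "age level")
  few <- subset_samples(tab, tab$meta$replicate %in% c("r01", "r02"))
  expect_error(loro_predictions(few), ">= 3 replicate")
})

test_that("between-regime prediction enforces disjoint regimes", {
  norm <- shared_norm$norm
  a_tab <- subset_samples(norm, norm$meta$regime == "A" &
                            norm$meta$age_days != 9)
  c_tab <- subset_samples(norm, norm$meta$regime == "C")
  expect_error(between_regime_predictions(c_tab, c_tab), "share regime")
  mismatch <- a_tab
  mismatch$values <- mismatch$values[, -1]
  expect_error(between_regime_predictions(c_tab, mismatch),
               "columns differ")
  res <- between_regime_predictions(c_tab, a_tab, seed = 2,
                                    alpha_grid = c(0.5, 1), nlambda = 30)
  expect_setequal(res$predictions$sample_id, a_tab$meta$sample_id)
  expect_true(all(res$predictions$mode == "between"))
  expect_equal(res$clock$regime, "C")
})

test_that("age acceleration recovers constructed coefficients exactly", {
  ages <- rep(c(21, 28, 35), each = 4)
  within <- data.frame(sample_id = sprintf("w%d", seq_along(ages)),
                       replicate = "r1", age_days = ages,
                       predicted = ages, mode = "within",
                       sample_regime = "C", clock_regime = "C")
  class(within) <- c("age_prediction_set", "data.frame")
  between <- within
  between$sample_id <- sprintf("b%d", seq_along(ages))
  between$predicted <- 5 + 1.5 * ages
  between$mode <- "between"
  # suppressed: summary.lm warns on the deliberately perfect fit
  fit <- suppressWarnings(fit_age_acceleration(within, between))
  expect_equal(unname(coef(fit)), c(0, 1, 5, 0.5), tolerance = 1e-10)
  # duplicated between set: no mode effects at all
  dup <- within
  dup$mode <- "between"
  fit0 <- suppressWarnings(fit_age_acceleration(within, dup))
  expect_equal(unname(coef(fit0)[c("beta2", "beta3")]), c(0, 0),
               tolerance = 1e-10)
  # fitted + residuals reproduce the predictions exactly
  expect_equal(unname(fitted(fit) + residuals(fit)), fit$data$predicted)
  # degenerate age structure is refused
  flat <- within[within$age_days == 21, ]
  expect_error(fit_age_acceleration(flat, between), "distinct")
})

test_that("feature comparison reproduces 2x2 arithmetic and edge cases", {
  panel <- sprintf("m%03d", 1:202)
  shared <- panel[1:4]
  a_feats <- panel[1:62]                      # 4 shared + 58 unique
  c_feats <- c(shared, panel[63:81])          # 4 shared + 19 unique
  fc <- compare_features(fake_clock(a_feats, panel, regime = "A"),
                         fake_clock(c_feats, panel, regime = "C"),
                         panel_size = 202)
  expect_equal(fc$table["yes", "yes"], 4)
  expect_equal(fc$table["yes", "no"], 58)    # A-clock only
  expect_equal(fc$table["no", "yes"], 19)    # C-clock only
  expect_equal(fc$table["no", "no"], 121)
  expect_equal(fc$odds_ratio, (4 * 121) / (58 * 19))
  expect_equal(round(fc$odds_ratio, 2), 0.44)
  expect_equal(sum(fc$table), 202)
  # margins equal the per-clock feature counts
  expect_equal(unname(rowSums(fc$table)[1]), 62)
  expect_equal(unname(colSums(fc$table)[1]), 23)
  # identical feature sets
  same <- compare_features(fake_clock(a_feats, panel),
                           fake_clock(a_feats, panel), 202)
  expect_equal(same$odds_ratio, Inf)
  expect_equal(same$n_shared, 62)
  # disjoint sets
  disj <- compare_features(fake_clock(panel[1:5], panel),
                           fake_clock(panel[6:10], panel), 202)
  expect_equal(disj$odds_ratio, 0)
  expect_true(is.na(disj$coef_correlation))
  expect_error(compare_features(fake_clock(panel[1:100], panel),
                                fake_clock(panel[101:200], panel),
                                panel_size = 150), "panel_size")
})

test_that("within-regime clock R2 rises with the latent aging slope", {
  r2_at <- function(slope, seed) {
    cfg <- sim_config(n_metabolites = 60,
                      ages_by_regime = list(A = c(21, 28, 35),
                                            C = c(21, 28, 35, 70)),
                      latent_aging_slope = c(A = 2 * slope, C = slope))
    sim <- simulate_metabolome(cfg, seed = seed)
    norm <- normalize_abundance(sim$table)
    c_tab <- subset_samples(norm, norm$meta$regime == "C")
    p <- loro_predictions(c_tab, seed = seed, alpha_grid = 1, nlambda = 30)
    r_squared(p$age_days, p$predicted)
  }
  r2 <- vapply(c(0.002, 0.008, 0.03), function(s)
    mean(vapply(1:2, function(sd) r2_at(s, 400 + sd), 1)), 1)
  expect_true(all(diff(r2) > 0))
})
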