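# shared fixtures and independent oracles, built in code at test time

# study-shaped config with a small metabolite panel for fast tests
tiny_config <- function(n_metabolites = 40, ...) {
  sim_config(n_metabolites = n_metabolites, ...)
}

# the fast-aging scenario: A ages at twice the latent rate of C, moderate
# noise, 10 replicates per regime, common ages plus the C day-70 samples
fast_aging_config <- function(n_metabolites = 202, ...) {
  sim_config(n_metabolites = n_metabolites,
             ages_by_regime = list(A = c(21, 28, 35), C = c(21, 28, 35, 70)),
             latent_aging_slope = c(A = 0.04, C = 0.02), ...)
}

# one full clock-and-acceleration analysis; returns the two beta3 estimates
run_clock_scenario <- function(seed, n_metabolites = 202,
                               alpha_grid = c(0.2, 0.6, 1), nlambda = 40) {
  sim <- simulate_metabolome(fast_aging_config(n_metabolites), seed = seed)
  norm <- normalize_abundance(sim$table)
  a <- subset_samples(norm, norm$meta$regime == "A")
  c_ <- subset_samples(norm, norm$meta$regime == "C")
  wa <- loro_predictions(a, seed = seed, alpha_grid = alpha_grid,
                         nlambda = nlambda)
  wc <- loro_predictions(c_, seed = seed + 50, alpha_grid = alpha_grid,
                         nlambda = nlambda)
  ba <- between_regime_predictions(c_, a, seed = seed + 100,
                                   alpha_grid = alpha_grid,
                                   nlambda = nlambda)
  bc <- between_regime_predictions(a, c_, seed = seed + 150,
                                   alpha_grid = alpha_grid,
                                   nlambda = nlambda)
  c(beta3_c_clock = unname(coef(fit_age_acceleration(wc, ba$predictions))["beta3"]),
    beta3_a_clock = unname(coef(fit_age_acceleration(wa, bc$predictions))["beta3"]),
    r2_within_a = r_squared(wa$age_days, wa$predicted),
    r2_within_c = r_squared(wc$age_days, wc$predicted))
}

# brute-force Benjamini-Hochberg step-up: largest k with p_(k) <= k q / m
# rejects hypotheses 1..k; adjusted p from the step-up recursion
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- prev
  }
  adj
}

# rows drawn around k equidistant centroids (scaled unit vectors), for
# planted-K recovery
planted_blobs <- function(k = 4, per = 20, d = 6, sep = 15, sd = 0.5,
                          seed = 1) {
  stopifnot(d >= k)
  set.seed(seed)
  centers <- sep * diag(k)
  centers <- cbind(centers, matrix(0, k, d - k))
  x <- centers[rep(seq_len(k), each = per), ] +
    matrix(stats::rnorm(k * per * d, sd = sd), k * per, d)
  rownames(x) <- sprintf("row_%02d", seq_len(k * per))
  list(x = x, truth = rep(seq_len(k), each = per))
}

# a clock object with prescribed features/coefficients, for feature
# comparison arithmetic on printed counts
fake_clock <- function(features, panel, coefs = NULL, regime = NA) {
  beta <- stats::setNames(numeric(length(panel)), panel)
  if (is.null(coefs)) coefs <- seq_along(features) / 10
  beta[features] <- coefs
  metaboclock:::new_metabolomic_clock(
    beta = beta, intercept = 0, center = beta * 0, scale = beta * 0 + 1,
    alpha = 0.5, lambda = 0.1, regime = regime)
}

# small normalized dataset reused across tests
shared_norm <- local({
  sim <- simulate_metabolome(sim_config(n_metabolites = 40), seed = 42)
  list(raw = sim$table, truth = sim$truth,
       norm = normalize_abundance(sim$table))
})
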