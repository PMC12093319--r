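#' Covariance-matrix PCA of the normalized metabolome
#'
#' Principal components of the sample-by-metabolite matrix computed on the
#' covariance matrix (metabolites centered but not rescaled to unit
#' variance), restricted to the ages sampled in both regimes so scores are
#' directly comparable.
#'
#' @param table a normalized [abundance_table()].
#' @param ages ages (days from egg) to retain; default the common ages.
#'   Every requested age must be present in both regimes.
#' @return an object of class `pc_model`: list with `loadings`
#'   (metabolite x component), `scores` (sample x component),
#'   `eigenvalues`, `var_explained`, `meta` (metadata of retained
#'   samples), `center`.
#' @export
pca_covariance <- function(table, ages = c(21, 28, 35)) {
  stopifnot(inherits(table, "abundance_table"))
  for (rg in unique(table$meta$regime)) {
    have <- unique(table$meta$age_days[table$meta$regime == rg])
    if (!all(ages %in% have)) {
      stop("regime ", rg, " lacks requested age(s): ",
           paste(setdiff(ages, have), collapse = ", "))
    }
  }
  keep <- table$meta$age_days %in% ages
  sub <- subset_samples(table, keep)
  if (nrow(sub$values) < 2) stop("need at least 2 samples for PCA")
  pc <- stats::prcomp(sub$values, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  structure(list(loadings = pc$rotation, scores = pc$x, eigenvalues = ev,
                 var_explained = ev / sum(ev), meta = sub$meta,
                 center = pc$center),
            class = "pc_model")
}

#' @export
print.pc_model <- function(x, ...) {
  k <- min(4, length(x$var_explained))
  cat("<pc_model> ", nrow(x$scores), " samples, ", ncol(x$scores),
      " components; PC1..PC", k, " explain ",
      round(100 * sum(x$var_explained[1:k]), 1), "% of variance\n",
      sep = "")
  invisible(x)
}

# Type-II style likelihood-ratio p-value layout for score ~ age * regime *
# history + (1|replicate). For each fixed-effect term, the reduced model
# drops the term and every higher-order term containing it; the comparison
# model adds the term back. Fitted once as templates, then refitted per
# response.
.divergence_terms <- list(
  "age"                = c("regime + history + regime:history",
                           "age + regime + history + regime:history"),
  "regime"             = c("age + history + age:history",
                           "age + regime + history + age:history"),
  "history"            = c("age + regime + age:regime",
                           "age + regime + history + age:regime"),
  "age:regime"         = c("age * history + regime + regime:history",
                           "age * history + regime + regime:history + age:regime"),
  "age:history"        = c("age * regime + history + regime:history",
                           "age * regime + history + regime:history + age:history"),
  "regime:history"     = c("age * regime + age:history + history",
                           "age * regime + age:history + history + regime:history"),
  "age:regime:history" = c("(age + regime + history)^2",
                           "age * regime * history"))

.lmer_quiet <- function(formula, data) {
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            check.conv.grad = "ignore",
                            calc.derivs = FALSE)
  suppressMessages(suppressWarnings(
    lme4::lmer(formula, data = data, REML = FALSE, control = ctrl)))
}

.refit_quiet <- function(model, y) {
  suppressMessages(suppressWarnings(lme4::refit(model, newresp = y)))
}

#' Mixed-model divergence test on principal components
#'
#' For each of the first `n_components` PCs, fits the score on the fixed
#' effects age x regime x history (age as a categorical factor) with a
#' random replicate intercept, and derives per-term p-values by
#' likelihood-ratio tests of nested maximum-likelihood fits. Divergence of
#' the two selection histories is declared when any component shows a
#' regime-by-history or regime-by-history-by-age effect at raw p < `alpha`
#' -- a deliberately liberal, unadjusted criterion, since divergence is the
#' outcome the convergence hypothesis must survive. Bonferroni-adjusted
#' p-values over the tested components are also reported for main-effect
#' interpretation.
#'
#' @param pcs a [pca_covariance()] result.
#' @param n_components number of leading components to test (default 12).
#' @param alpha raw significance level for the divergence criterion.
#' @return an object of class `pc_divergence`: list with `p_values`
#'   (component x term matrix), `p_bonferroni`, `divergence`
#'   (logical), `triggering` (data frame of component/term hits),
#'   `n_components`, `alpha`.
#' @export
test_pc_divergence <- function(pcs, n_components = 12, alpha = 0.05) {
  stopifnot(inherits(pcs, "pc_model"))
  n_components <- min(n_components, ncol(pcs$scores))
  meta <- pcs$meta
  need <- c("age_days", "regime", "history", "replicate")
  if (!all(need %in% names(meta))) {
    stop("metadata must contain: ", paste(need, collapse = ", "))
  }
  d <- data.frame(age = factor(meta$age_days),
                  regime = factor(meta$regime),
                  history = factor(meta$history),
                  replicate = factor(meta$replicate))
  cells <- table(d$regime, d$history, d$age)
  if (any(cells == 0)) stop("empty (regime, history, age) design cell(s)")

  d$y <- pcs$scores[, 1]
  templates <- lapply(.divergence_terms, function(forms) {
    list(reduced = .lmer_quiet(stats::as.formula(
           paste("y ~", forms[1], "+ (1|replicate)")), d),
         full = .lmer_quiet(stats::as.formula(
           paste("y ~", forms[2], "+ (1|replicate)")), d))
  })

  terms <- names(.divergence_terms)
  p <- matrix(NA_real_, n_components, length(terms),
              dimnames = list(paste0("PC", seq_len(n_components)), terms))
  for (k in seq_len(n_components)) {
    y <- pcs$scores[, k]
    for (tm in terms) {
      m0 <- .refit_quiet(templates[[tm]]$reduced, y)
      m1 <- .refit_quiet(templates[[tm]]$full, y)
      lr <- 2 * (as.numeric(stats::logLik(m1)) -
                 as.numeric(stats::logLik(m0)))
      df <- attr(stats::logLik(m1), "df") - attr(stats::logLik(m0), "df")
      p[k, tm] <- stats::pchisq(max(lr, 0), df = df, lower.tail = FALSE)
    }
  }
  p_bonf <- pmin(1, p * n_components)
  hit <- p[, c("regime:history", "age:regime:history"), drop = FALSE] < alpha
  trig <- which(hit, arr.ind = TRUE)
  triggering <- data.frame(
    component = rownames(p)[trig[, 1]],
    term = c("regime:history", "age:regime:history")[trig[, 2]],
    p = p[, c("regime:history", "age:regime:history")][trig],
    stringsAsFactors = FALSE)
  structure(list(p_values = p, p_bonferroni = p_bonf,
                 divergence = any(hit), triggering = triggering,
                 n_components = n_components, alpha = alpha),
            class = "pc_divergence")
}

#' @export
print.pc_divergence <- function(x, ...) {
  cat("<pc_divergence> first ", x$n_components, " PCs, alpha = ", x$alpha,
      "\n  divergence declared: ", x$divergence, sep = "")
  if (x$divergence) {
    cat(" (", nrow(x$triggering), " component-term hit(s))", sep = "")
  }
  cat("\n")
  invisible(x)
}
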