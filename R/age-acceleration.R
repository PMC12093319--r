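#' Age-acceleration model comparing within- and between-regime predictions
#'
#' Ordinary least squares of predicted age on chronological age, a 0/1
#' prediction-mode indicator (0 = within-regime leave-one-replicate-out,
#' 1 = between-regime), and their interaction:
#'
#' `predicted ~ alpha + beta1 * age + beta2 * mode + beta3 * age:mode`
#'
#' `beta2` measures an age-independent shift in apparent (biological) age
#' of the target regime as seen by the other regime's clock, and `beta3`
#' the difference in apparent aging *rate*: a positive `beta3` means the
#' between-regime samples' metabolome changes faster per chronological day
#' than the clock's own regime. Conventional t-based p-values are
#' reported.
#'
#' @param within an `age_prediction_set` with mode `"within"` (from
#'   [loro_predictions()]).
#' @param between an `age_prediction_set` with mode `"between"` (from
#'   [between_regime_predictions()]).
#' @return an object of class `age_acceleration`: list with `coefficients`
#'   (named alpha/beta1/beta2/beta3), `table` (coefficient matrix with
#'   standard errors, t values, p-values), `sigma2` (residual variance),
#'   `fit` (the underlying `lm`), and `data`.
#' @export
fit_age_acceleration <- function(within, between) {
  if (nrow(within) == 0 || nrow(between) == 0) {
    stop("both prediction sets must be non-empty")
  }
  if (length(unique(within$age_days)) < 2 ||
      length(unique(between$age_days)) < 2) {
    stop("each prediction mode needs >= 2 distinct chronological ages")
  }
  d <- rbind(as.data.frame(within), as.data.frame(between))
  d$mode_between <- as.numeric(d$mode == "between")
  fit <- stats::lm(predicted ~ age_days * mode_between, data = d)
  tab <- summary(fit)$coefficients
  rownames(tab) <- c("alpha", "beta1", "beta2", "beta3")
  cf <- tab[, 1]
  names(cf) <- rownames(tab)
  structure(list(coefficients = cf, table = tab,
                 sigma2 = summary(fit)$sigma^2, fit = fit, data = d),
            class = "age_acceleration")
}

#' @export
coef.age_acceleration <- function(object, ...) object$coefficients

#' @export
print.age_acceleration <- function(x, ...) {
  cat("<age_acceleration> within (n=",
      sum(x$data$mode_between == 0), ") vs between (n=",
      sum(x$data$mode_between == 1), ") predictions\n", sep = "")
  print(round(x$table, 4))
  invisible(x)
}

#' @export
summary.age_acceleration <- function(object, ...) {
  object$table
}

#' @export
residuals.age_acceleration <- function(object, ...) {
  stats::residuals(object$fit)
}

#' @export
fitted.age_acceleration <- function(object, ...) {
  stats::fitted(object$fit)
}

#' Compare the feature sets of two clocks
#'
#' Given the A-type and C-type clocks fit on the same metabolite panel,
#' reports: feature counts and their intersection; Fisher's exact test on
#' the 2x2 membership table (both / A-only / C-only / neither, summing to
#' the panel size), with the sample odds ratio `(both * neither) /
#' (A_only * C_only)`; the Pearson correlation of the shared features'
#' coefficients (needs >= 3 shared features, otherwise `NA`); and
#' Wilcoxon rank-sum tests comparing |beta| of shared versus clock-unique
#' features within each clock.
#'
#' @param clock_a,clock_c [fit_clock()] models on the same panel.
#' @param panel_size total number of metabolites in the panel (defaults to
#'   the panel the clocks were fit on).
#' @return an object of class `feature_comparison`.
#' @export
compare_features <- function(clock_a, clock_c,
                             panel_size = length(clock_a$beta)) {
  fa <- clock_a$features
  fc <- clock_c$features
  shared <- intersect(fa, fc)
  n_union <- length(union(fa, fc))
  if (panel_size < n_union) {
    stop("panel_size (", panel_size, ") smaller than the union of ",
         "feature sets (", n_union, ")")
  }
  tab <- matrix(c(length(shared),              # in both clocks
                  length(fc) - length(shared), # C only
                  length(fa) - length(shared), # A only
                  panel_size - n_union),       # neither
                nrow = 2,
                dimnames = list(in_a = c("yes", "no"),
                                in_c = c("yes", "no")))
  or <- (tab["yes", "yes"] * tab["no", "no"]) /
    (tab["yes", "no"] * tab["no", "yes"])
  fisher <- stats::fisher.test(tab)
  rho <- NA_real_; rho_p <- NA_real_
  if (length(shared) >= 3) {
    ct <- stats::cor.test(clock_a$beta[shared], clock_c$beta[shared],
                          method = "pearson")
    rho <- unname(ct$estimate); rho_p <- ct$p.value
  }
  rank_test <- function(clock) {
    uniq <- setdiff(clock$features, shared)
    if (length(shared) == 0 || length(uniq) == 0) return(NULL)
    stats::wilcox.test(abs(clock$beta[shared]), abs(clock$beta[uniq]))
  }
  structure(list(n_a = length(fa), n_c = length(fc),
                 n_shared = length(shared), shared = shared,
                 panel_size = panel_size, table = tab,
                 odds_ratio = or, fisher_p = fisher$p.value,
                 coef_correlation = rho, coef_correlation_p = rho_p,
                 ranksum_a = rank_test(clock_a),
                 ranksum_c = rank_test(clock_c)),
            class = "feature_comparison")
}

#' @export
print.feature_comparison <- function(x, ...) {
  cat("<feature_comparison> panel ", x$panel_size, ": A-clock ", x$n_a,
      ", C-clock ", x$n_c, ", shared ", x$n_shared, "\n", sep = "")
  cat("  odds ratio ", round(x$odds_ratio, 2), " (Fisher p = ",
      signif(x$fisher_p, 3), ")\n", sep = "")
  if (!is.na(x$coef_correlation)) {
    cat("  shared-coefficient Pearson r = ",
        round(x$coef_correlation, 3), " (p = ",
        signif(x$coef_correlation_p, 3), ")\n", sep = "")
  }
  invisible(x)
}
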