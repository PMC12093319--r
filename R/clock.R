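#' Fit an elastic-net metabolomic age clock
#'
#' Penalized linear regression of chronological age (days from egg) on
#' metabolite abundances. Predictors are standardized to zero mean and
#' unit variance *within the training set*, and the standardization
#' parameters are stored in the model so held-out samples are transformed
#' with training statistics only (no leakage). The penalty pair is chosen
#' over a dense grid -- mixing parameter alpha in `alpha_grid` crossed with
#' a log-spaced path of `nlambda` penalty strengths running from the
#' smallest lambda that zeroes every coefficient down
#' `-log10(lambda_min_ratio)` decades -- as the pair with the lowest root
#' mean squared error under seeded k-fold cross-validation.
#'
#' @param table a normalized [abundance_table()]; ages are taken from the
#'   `age_days` metadata column and must vary.
#' @param folds number of CV folds (default 5).
#' @param seed integer seed for fold assignment.
#' @param alpha_grid candidate L1 mixing fractions (1 = lasso, 0 = ridge).
#' @param nlambda penalty-path length per alpha.
#' @param lambda_min_ratio smallest lambda as a fraction of lambda-max.
#' @param regime optional training-regime label stored in the model
#'   (defaults to the unique regime of the training samples, if unique).
#' @return an object of class `metabolomic_clock`: list with `beta`
#'   (named coefficient vector on the standardized predictor scale),
#'   `intercept`, `center`, `scale`, `alpha`, `lambda`, `cv_rmse`,
#'   `features` (metabolites with nonzero coefficients), `regime`,
#'   `metabolites`, `n_train`.
#' @export
fit_clock <- function(table, folds = 5, seed = 1,
                      alpha_grid = seq(0.1, 1, by = 0.1), nlambda = 100,
                      lambda_min_ratio = 1e-4, regime = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  y <- table$meta$age_days
  x <- table$values
  if (stats::var(y) == 0) stop("age has zero variance; cannot fit a clock")
  if (nrow(x) < folds) stop("fewer samples than CV folds")

  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1   # constant columns carry no signal; leave unscaled
  xs <- sweep(sweep(x, 2, ctr), 2, scl, `/`)

  set.seed(seed)
  # fold ids keyed to sorted sample identifiers, so the fit does not
  # depend on the row order of the input table
  ids <- rownames(xs)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(xs)))
  foldid <- sample(rep_len(seq_len(folds), nrow(xs)))[rank(ids,
                                                           ties.method = "first")]
  best <- NULL
  rmse_seen <- c()
  for (a in alpha_grid) {
    cv <- glmnet::cv.glmnet(xs, y, alpha = a, foldid = foldid,
                            standardize = FALSE, nlambda = nlambda,
                            lambda.min.ratio = lambda_min_ratio,
                            type.measure = "mse")
    rmse <- sqrt(cv$cvm)
    rmse_seen <- c(rmse_seen, rmse)
    i <- which.min(rmse)
    if (is.null(best) || rmse[i] < best$rmse) {
      best <- list(cv = cv, alpha = a, lambda = cv$lambda[i],
                   rmse = rmse[i])
    }
  }
  if (length(unique(signif(rmse_seen, 12))) == 1) {
    stop("all candidate penalty pairs give identical CV RMSE; ",
         "input is degenerate")
  }
  cf <- as.matrix(stats::coef(best$cv, s = best$lambda))
  beta <- cf[-1, 1]
  names(beta) <- colnames(xs)
  if (is.null(regime)) {
    rg <- unique(table$meta$regime)
    regime <- if (length(rg) == 1) rg else NA_character_
  }
  new_metabolomic_clock(beta = beta, intercept = cf[1, 1], center = ctr,
                        scale = scl, alpha = best$alpha,
                        lambda = best$lambda, cv_rmse = best$rmse,
                        regime = regime, n_train = nrow(xs))
}

# low-level constructor; also used by tests to probe limiting behaviour
new_metabolomic_clock <- function(beta, intercept, center, scale, alpha,
                                  lambda, cv_rmse = NA_real_,
                                  regime = NA_character_, n_train = NA) {
  structure(list(beta = beta, intercept = intercept, center = center,
                 scale = scale, alpha = alpha, lambda = lambda,
                 cv_rmse = cv_rmse, regime = regime,
                 metabolites = names(beta),
                 features = names(beta)[beta != 0], n_train = n_train),
            class = "metabolomic_clock")
}

#' @export
print.metabolomic_clock <- function(x, ...) {
  cat("<metabolomic_clock>", if (!is.na(x$regime))
    paste0(" [", x$regime, "-clock]") else "", "\n", sep = "")
  cat("  ", length(x$features), " of ", length(x$beta),
      " metabolites with nonzero coefficients\n", sep = "")
  cat("  alpha = ", x$alpha, ", lambda = ", signif(x$lambda, 4),
      ", CV RMSE = ", signif(x$cv_rmse, 4), " days\n", sep = "")
  invisible(x)
}

#' @export
coef.metabolomic_clock <- function(object, nonzero = FALSE, ...) {
  b <- c("(Intercept)" = object$intercept, object$beta)
  if (nonzero) b <- b[c(TRUE, object$beta != 0)]
  b
}

#' Predict age from a fitted metabolomic clock
#'
#' Applies the clock's stored training standardization to new samples and
#' returns predicted ages in days from egg.
#'
#' @param object a [fit_clock()] model.
#' @param newdata an [abundance_table()] or numeric matrix with the
#'   training metabolite columns.
#' @param ... unused.
#' @return numeric vector of predicted ages.
#' @export
predict.metabolomic_clock <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "abundance_table")) newdata$values else
    as.matrix(newdata)
  missing <- setdiff(object$metabolites, colnames(x))
  if (length(missing) > 0) {
    stop("missing metabolite column(s): ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) " ..." else "")
  }
  x <- x[, object$metabolites, drop = FALSE]
  xs <- sweep(sweep(x, 2, object$center), 2, object$scale, `/`)
  drop(xs %*% object$beta) + object$intercept
}

#' Coefficient of determination of age predictions
#'
#' `1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`; can be negative when
#' predictions do worse than the mean age.
#'
#' @param actual chronological ages (non-constant, length >= 2).
#' @param predicted predicted ages, same length.
#' @return a single number.
#' @export
r_squared <- function(actual, predicted) {
  if (length(actual) != length(predicted)) stop("length mismatch")
  if (length(actual) < 2) stop("need at least 2 observations")
  if (stats::var(actual) == 0) stop("actual ages are constant")
  1 - sum((actual - predicted)^2) / sum((actual - mean(actual))^2)
}
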