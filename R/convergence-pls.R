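#' Train a partial least-squares regime discriminator
#'
#' Two-component PLS discriminant model for selection regime, fit as a
#' latent-projection regression of a 0/1 class response (1 = regime
#' `positive_class`) on the metabolite matrix. Class probabilities are the
#' continuous predictions clipped to [0, 1]; the class decision is made at
#' probability 0.5. Cross-validated accuracy is computed over seeded,
#' regime-stratified folds; training (resubstitution) accuracy and the
#' training ROC curve/AUC are reported from the final model fit on all
#' supplied samples. Typical use trains on the long-standing populations
#' at the common ages and tests transfer to the recently derived ones.
#'
#' @param table a normalized [abundance_table()] already restricted to the
#'   intended training samples (e.g. long-standing populations).
#' @param ages ages to train on (default the common ages 21/28/35).
#' @param n_components number of latent components (default 2).
#' @param folds cross-validation folds (default 5).
#' @param seed integer seed for fold assignment.
#' @param positive_class regime coded 1 (default `"A"`).
#' @return an object of class `regime_discriminator`: list with `fit`
#'   (the mixOmics pls object), `metabolites`, `positive_class`,
#'   `threshold`, `train_accuracy`, `cv_accuracy`, `roc`
#'   (pROC object), `auc`, `train_prob`.
#' @export
train_regime_discriminator <- function(table, ages = c(21, 28, 35),
                                       n_components = 2, folds = 5,
                                       seed = 1, positive_class = "A") {
  stopifnot(inherits(table, "abundance_table"))
  sub <- subset_samples(table, table$meta$age_days %in% ages)
  x <- sub$values
  y <- as.numeric(sub$meta$regime == positive_class)
  if (min(table(y)) < 2) stop("need >= 2 samples per regime")

  set.seed(seed)
  # stratified fold ids: shuffle within class, deal out folds round-robin
  foldid <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    foldid[idx] <- rep_len(seq_len(folds), length(idx))
  }
  cv_pred <- rep(NA_real_, length(y))
  for (f in seq_len(folds)) {
    tr <- foldid != f
    if (length(unique(y[tr])) < 2) {
      stop("fold ", f, " lost a class entirely; reseed or reduce folds")
    }
    m <- suppressMessages(mixOmics::pls(x[tr, , drop = FALSE],
                                        matrix(y[tr], ncol = 1),
                                        ncomp = n_components,
                                        mode = "regression"))
    pr <- predict(m, x[!tr, , drop = FALSE])$predict[, 1, n_components]
    cv_pred[!tr] <- pmin(1, pmax(0, pr))
  }
  cv_accuracy <- mean((cv_pred >= 0.5) == (y == 1))

  fit <- suppressMessages(mixOmics::pls(x, matrix(y, ncol = 1),
                                        ncomp = n_components,
                                        mode = "regression"))
  prob <- pmin(1, pmax(0, predict(fit, x)$predict[, 1, n_components]))
  train_accuracy <- mean((prob >= 0.5) == (y == 1))
  roc <- suppressMessages(pROC::roc(response = y, predictor = prob,
                                    quiet = TRUE, direction = "<"))
  structure(list(fit = fit, metabolites = colnames(x),
                 positive_class = positive_class, threshold = 0.5,
                 n_components = n_components,
                 train_accuracy = train_accuracy,
                 cv_accuracy = cv_accuracy,
                 roc = roc, auc = as.numeric(pROC::auc(roc)),
                 train_prob = prob),
            class = "regime_discriminator")
}

#' @export
print.regime_discriminator <- function(x, ...) {
  cat("<regime_discriminator> ", x$n_components, "-component PLS; ",
      "training accuracy ", round(100 * x$train_accuracy, 1), "%, CV ",
      round(100 * x$cv_accuracy, 1), "%, AUC ", round(x$auc, 3), "\n",
      sep = "")
  invisible(x)
}

#' Predict selection regime for held-out samples
#'
#' @param object a [train_regime_discriminator()] model.
#' @param held_out an [abundance_table()] with the same metabolite columns
#'   as the training data.
#' @param ... unused.
#' @return a list with `prob` (per-sample probability of the positive
#'   class), `class` (predicted regime labels), and, when the metadata
#'   carries regime labels, `accuracy`.
#' @export
predict.regime_discriminator <- function(object, held_out, ...) {
  stopifnot(inherits(held_out, "abundance_table"))
  missing <- setdiff(object$metabolites, colnames(held_out$values))
  if (length(missing) > 0) {
    stop("held-out table lacks metabolite column(s): ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) " ..." else "")
  }
  x <- held_out$values[, object$metabolites, drop = FALSE]
  pr <- predict(object$fit, x)$predict[, 1, object$n_components]
  prob <- pmin(1, pmax(0, pr))
  neg <- setdiff(unique(c("A", "C", held_out$meta$regime)),
                 object$positive_class)[1]
  cls <- ifelse(prob >= object$threshold, object$positive_class, neg)
  out <- list(prob = prob, class = cls)
  if ("regime" %in% names(held_out$meta)) {
    out$accuracy <- mean(cls == held_out$meta$regime)
  }
  out
}
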