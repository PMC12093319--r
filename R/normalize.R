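#' Drop metabolites with missing values
#'
#' Restricts a raw abundance table to the metabolites that have a value in
#' every sample; targeted LC-MS panels routinely detect a metabolite in only
#' a subset of samples, and such incomplete columns are removed rather than
#' imputed. Column order is preserved.
#'
#' @param table a raw [abundance_table()].
#' @return an `abundance_table` (still stage `"raw"`) with complete columns
#'   only.
#' @export
filter_complete <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$stage != "raw") stop("filter_complete() expects a raw table")
  complete <- colSums(is.na(table$values)) == 0
  if (!any(complete)) stop("no metabolite has a value in every sample")
  abundance_table(table$values[, complete, drop = FALSE], table$meta,
                  stage = "raw")
}

#' Log-transform and center within sample
#'
#' Natural-log transforms positive abundances (to approximate Gaussian
#' residuals) and then subtracts each sample's row mean, removing
#' sample-to-sample loading differences. Every row of the result has mean
#' zero (|mean| < 1e-9).
#'
#' @param table an [abundance_table()] at stage `"raw"` or `"logged"` with
#'   strictly positive values and no missing values.
#' @return an `abundance_table` at stage `"centered"`.
#' @export
log_center <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  stage <- .advance_stage(table, c("raw", "logged"), "centered")
  v <- table$values
  if (anyNA(v)) stop("missing values present; run filter_complete() first")
  bad <- which(v <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    cells <- apply(utils::head(bad, 5), 1, function(ij)
      paste0(rownames(v)[ij[1]], "/", colnames(v)[ij[2]]))
    stop("non-positive values cannot be log-transformed; offending cells: ",
         paste(cells, collapse = ", "),
         if (nrow(bad) > 5) sprintf(" (and %d more)", nrow(bad) - 5) else "")
  }
  lv <- log(v)
  lv <- lv - rowMeans(lv)
  abundance_table(lv, table$meta, stage = stage)
}

#' Remove LC-MS batch effects by residualization
#'
#' Fits, independently for every metabolite, a least-squares model of
#' abundance on batch as a categorical main effect and keeps the residuals.
#' Because the batch factor spans an intercept, per-batch (and hence
#' overall) means of each metabolite are zero in the output.
#'
#' @param table a centered [abundance_table()] whose metadata has a `batch`
#'   column; every batch must contain at least two samples.
#' @return an `abundance_table` at stage `"normalized"`.
#' @export
batch_residualize <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  stage <- .advance_stage(table, c("centered", "normalized"), "normalized")
  if (!"batch" %in% names(table$meta)) stop("metadata has no `batch` column")
  batch <- factor(table$meta$batch)
  sizes <- table(batch)
  if (any(sizes < 2)) {
    stop("singleton batch(es): ", paste(names(sizes)[sizes < 2],
         collapse = ", "), "; merge batches before residualizing")
  }
  # residuals of y ~ batch are y minus the batch means, computed per column
  v <- table$values
  for (b in levels(batch)) {
    idx <- batch == b
    v[idx, ] <- sweep(v[idx, , drop = FALSE], 2,
                      colMeans(v[idx, , drop = FALSE]))
  }
  abundance_table(v, table$meta, stage = stage)
}

#' Run the full normalization chain
#'
#' Convenience wrapper: [filter_complete()], then [log_center()], then
#' [batch_residualize()].
#'
#' @param table a raw [abundance_table()].
#' @return a normalized `abundance_table`.
#' @export
normalize_abundance <- function(table) {
  batch_residualize(log_center(filter_complete(table)))
}

#' Technical-replicate coefficient of variation
#'
#' Quality-control summary of assay reproducibility: for a table whose rows
#' are repeated technical injections of the same pooled sample, computes the
#' per-metabolite coefficient of variation (sample standard deviation over
#' mean, on the provided scale) and its mean and range.
#'
#' @param replicate_table an [abundance_table()] with at least two rows of
#'   technical replicates.
#' @return an object of class `qc_report`: list with `cv` (named vector),
#'   `mean_cv`, `cv_range`.
#' @export
technical_cv <- function(replicate_table) {
  stopifnot(inherits(replicate_table, "abundance_table"))
  v <- replicate_table$values
  if (nrow(v) < 2) stop("need at least 2 technical replicate rows")
  mu <- colMeans(v)
  if (any(mu == 0)) {
    stop("zero mean for metabolite(s): ",
         paste(colnames(v)[mu == 0], collapse = ", "))
  }
  cv <- apply(v, 2, stats::sd) / mu
  structure(list(cv = cv, mean_cv = mean(cv), cv_range = range(cv)),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report> ", length(x$cv), " metabolites; mean CV ",
      signif(x$mean_cv, 3), ", range ", signif(x$cv_range[1], 3), " to ",
      signif(x$cv_range[2], 3), "\n", sep = "")
  invisible(x)
}
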