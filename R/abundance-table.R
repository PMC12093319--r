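#' Samples-by-metabolites abundance table
#'
#' The central data container: a numeric matrix of abundance values with one
#' row per pooled sample and one column per metabolite, paired with a sample
#' metadata data frame. A stage tag records how far the table has progressed
#' through the normalization chain and is only allowed to advance in the
#' order `raw -> logged -> centered -> normalized`.
#'
#' @param values numeric matrix, samples in rows, metabolites in columns.
#'   Row names are sample identifiers; column names are metabolite
#'   identifiers.
#' @param meta data frame of sample metadata with one row per matrix row.
#'   Recognised columns: `sample_id`, `regime` (`"A"` or `"C"`), `history`
#'   (`"long"` or `"recent"`), `replicate`, `age_days`, `batch`, `n_pooled`.
#' @param stage one of `"raw"`, `"logged"`, `"centered"`, `"normalized"`.
#' @return an object of class `abundance_table` with elements `values`,
#'   `meta` and `stage`.
#' @export
abundance_table <- function(values, meta, stage = "raw") {
  stage <- match.arg(stage, .stages)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("`values` must be a numeric matrix")
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (nrow(meta) != nrow(values)) {
    stop("metadata rows (", nrow(meta), ") must match matrix rows (",
         nrow(values), ")")
  }
  if (is.null(rownames(values)) && "sample_id" %in% names(meta)) {
    rownames(values) <- meta$sample_id
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("met_%03d", seq_len(ncol(values)))
  }
  structure(list(values = values, meta = meta, stage = stage),
            class = "abundance_table")
}

.stages <- c("raw", "logged", "centered", "normalized")

# assert that a stage transition moves forward in the pipeline order
.advance_stage <- function(table, allowed_from, to) {
  if (!table$stage %in% allowed_from) {
    stop("table is at stage '", table$stage, "'; expected one of: ",
         paste(allowed_from, collapse = ", "))
  }
  to
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("<abundance_table> ", nrow(x$values), " samples x ", ncol(x$values),
      " metabolites [stage: ", x$stage, "]\n", sep = "")
  vars <- intersect(c("regime", "history", "age_days", "batch"), names(x$meta))
  for (v in vars) {
    cat("  ", v, ": ", paste(names(table(x$meta[[v]])), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' Subset an abundance table by samples
#'
#' Keeps matrix rows and metadata rows aligned.
#'
#' @param table an [abundance_table()].
#' @param keep logical or integer index over samples.
#' @return an `abundance_table` at the same stage.
#' @export
subset_samples <- function(table, keep) {
  stopifnot(inherits(table, "abundance_table"))
  abundance_table(table$values[keep, , drop = FALSE],
                  table$meta[keep, , drop = FALSE],
                  stage = table$stage)
}

#' Write / read an abundance table as TSV
#'
#' The on-disk layout is one TSV with samples as rows: the reserved metadata
#' columns first (`sample_id`, `regime`, `history`, `replicate`, `age_days`,
#' `batch`, `n_pooled`, `stage`), then one column per metabolite.
#'
#' @param table an [abundance_table()].
#' @param path file path.
#' @return `write_abundance` returns `path` invisibly; `read_abundance`
#'   returns an `abundance_table`.
#' @export
write_abundance <- function(table, path) {
  stopifnot(inherits(table, "abundance_table"))
  meta <- table$meta
  meta$stage <- table$stage
  out <- cbind(meta, as.data.frame(table$values, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_abundance
#' @export
read_abundance <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  reserved <- intersect(
    c("sample_id", "regime", "history", "replicate", "age_days", "batch",
      "n_pooled", "stage"), names(raw))
  meta <- raw[reserved]
  stage <- if ("stage" %in% reserved) unique(meta$stage) else "raw"
  meta$stage <- NULL
  values <- as.matrix(raw[setdiff(names(raw), reserved)])
  rownames(values) <- meta$sample_id
  abundance_table(values, meta, stage = stage)
}
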