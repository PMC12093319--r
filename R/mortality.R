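#' Pool cohort death logs
#'
#' Day-wise sum of deaths across cohorts (e.g. the two caged cohorts of
#' one replicate population); alive counts are recomputed downstream from
#' the pooled totals, so pooling commutes with the mortality calculation.
#'
#' @param tables list of `death_count_table` data frames (columns
#'   `cohort`, `day`, `deaths`); cohort identifiers must not repeat
#'   across list elements.
#' @param id identifier for the pooled pseudo-cohort.
#' @return a `death_count_table` with a single cohort.
#' @export
pool_cohorts <- function(tables, id = "pooled") {
  stopifnot(is.list(tables), length(tables) >= 1)
  ids <- lapply(tables, function(t) unique(t$cohort))
  all_ids <- unlist(ids)
  if (anyDuplicated(all_ids)) {
    stop("overlapping cohort identifier(s): ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  }
  d <- do.call(rbind, lapply(tables, function(t)
    t[c("day", "deaths")]))
  agg <- stats::aggregate(deaths ~ day, data = d, FUN = sum)
  agg <- agg[order(agg$day), ]
  res <- data.frame(cohort = id, day = agg$day, deaths = agg$deaths,
                    stringsAsFactors = FALSE)
  class(res) <- c("death_count_table", "data.frame")
  res
}

#' Age-specific mortality from a death log
#'
#' For a cohort observed to extinction, the proportion of flies alive at
#' the start of day d that die on day d:
#' `M_d = (n_[d-1] - n_d) / n_[d-1]`, where `n_d` is the number alive at
#' the end of day d. Days after extinction are omitted; M lies in
#' [0, 1].
#'
#' @param table a `death_count_table` for one cohort (or pooled cohorts).
#' @param cohort_size initial number of flies; defaults to the total
#'   death count (i.e. the assay ran to completion).
#' @return a `mortality_series`: data frame with columns `day`, `M`,
#'   `n_start` (alive entering the day), `deaths`.
#' @export
age_specific_mortality <- function(table,
                                   cohort_size = sum(table$deaths)) {
  if (length(unique(table$cohort)) > 1) {
    stop("one cohort at a time; use pool_cohorts() first")
  }
  tab <- table[order(table$day), ]
  full_days <- seq_len(max(tab$day))
  deaths <- numeric(length(full_days))
  deaths[tab$day] <- tab$deaths
  n_end <- cohort_size - cumsum(deaths)
  n_start <- c(cohort_size, n_end[-length(n_end)])
  keep <- n_start > 0
  res <- data.frame(day = full_days[keep],
                    M = deaths[keep] / n_start[keep],
                    n_start = n_start[keep], deaths = deaths[keep])
  class(res) <- c("mortality_series", "data.frame")
  res
}
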