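#' Per-metabolite linear mixed models for selection and age effects
#'
#' Fits, for every metabolite, the mixed model
#' `abundance ~ Sel + Age + Sel:Age + (1 | Rep)` with selection regime and
#' (categorical) age as fixed effects and replicate population as a random
#' intercept. Per-term p-values come from likelihood-ratio chi-square
#' tests of nested maximum-likelihood fits (interaction: full vs.
#' additive; each main effect: additive vs. additive minus the term).
#' Benjamini-Hochberg adjustment is applied within each term across
#' metabolites and significance flagged at q < `fdr`.
#'
#' @param table a normalized [abundance_table()] with day-9 A-type samples
#'   already excluded; needs `regime`, `age_days`, `replicate` metadata
#'   and >= 2 replicates per regime.
#' @param fdr per-term Benjamini-Hochberg threshold (default 0.01).
#' @return an object of class `lmm_result_table`: data frame with one row
#'   per metabolite (`p_*`, `q_*`, `sig_*` for terms `selection`, `age`,
#'   `interaction`; `replicate_variance`; `converged`), with the threshold
#'   in attribute `fdr`.
#' @export
fit_metabolite_lmms <- function(table, fdr = 0.01) {
  stopifnot(inherits(table, "abundance_table"))
  meta <- table$meta
  d <- data.frame(sel = factor(meta$regime), age = factor(meta$age_days),
                  rep = factor(meta$replicate))
  for (rg in levels(d$sel)) {
    if (length(unique(d$rep[d$sel == rg])) < 2) {
      stop("regime ", rg, " has < 2 replicate populations")
    }
  }
  forms <- list(full = y ~ sel * age + (1 | rep),
                additive = y ~ sel + age + (1 | rep),
                no_sel = y ~ age + (1 | rep),
                no_age = y ~ sel + (1 | rep))
  d$y <- table$values[, 1]
  templates <- lapply(forms, function(f) .lmer_quiet(f, d))

  nm <- ncol(table$values)
  res <- data.frame(metabolite = colnames(table$values),
                    p_selection = NA_real_, p_age = NA_real_,
                    p_interaction = NA_real_,
                    replicate_variance = NA_real_, converged = FALSE,
                    stringsAsFactors = FALSE)
  lrt <- function(m1, m0) {
    lr <- 2 * (as.numeric(stats::logLik(m1)) -
               as.numeric(stats::logLik(m0)))
    df <- attr(stats::logLik(m1), "df") - attr(stats::logLik(m0), "df")
    stats::pchisq(max(lr, 0), df = df, lower.tail = FALSE)
  }
  for (j in seq_len(nm)) {
    y <- table$values[, j]
    fits <- tryCatch(lapply(templates, .refit_quiet, y = y),
                     error = function(e) NULL)
    if (is.null(fits)) next
    res$p_interaction[j] <- lrt(fits$full, fits$additive)
    res$p_selection[j] <- lrt(fits$additive, fits$no_sel)
    res$p_age[j] <- lrt(fits$additive, fits$no_age)
    vc <- lme4::VarCorr(fits$full)
    res$replicate_variance[j] <- as.numeric(vc$rep[1, 1])
    res$converged[j] <- TRUE
  }
  if (sum(res$converged) < 3) stop("fewer than 3 metabolites converged")
  for (tm in c("selection", "age", "interaction")) {
    p <- res[[paste0("p_", tm)]]
    q <- rep(NA_real_, nm)
    q[!is.na(p)] <- stats::p.adjust(p[!is.na(p)], method = "BH")
    res[[paste0("q_", tm)]] <- q
    res[[paste0("sig_", tm)]] <- !is.na(q) & q < fdr
  }
  attr(res, "fdr") <- fdr
  class(res) <- c("lmm_result_table", "data.frame")
  res
}

#' UpSet-style counts of significant metabolites per term combination
#'
#' @param results an [fit_metabolite_lmms()] table with flags computed.
#' @return a list with `per_term` (significant metabolites per term),
#'   `subsets` (named counts for each non-empty subset of
#'   selection/age/interaction, exclusive), and `total_significant`
#'   (unique metabolites significant for at least one term).
#' @export
term_overlap_counts <- function(results) {
  stopifnot(inherits(results, "lmm_result_table"))
  s <- results$sig_selection; a <- results$sig_age
  i <- results$sig_interaction
  subs <- c(
    "selection"               = sum(s & !a & !i),
    "age"                     = sum(!s & a & !i),
    "interaction"             = sum(!s & !a & i),
    "selection+age"           = sum(s & a & !i),
    "selection+interaction"   = sum(s & !a & i),
    "age+interaction"         = sum(!s & a & i),
    "selection+age+interaction" = sum(s & a & i))
  list(per_term = c(selection = sum(s), age = sum(a),
                    interaction = sum(i)),
       subsets = subs,
       total_significant = sum(s | a | i))
}

#' Group-mean abundance matrix
#'
#' Arithmetic mean of each metabolite within every (regime, age) group;
#' columns ordered regime-major, age-ascending and named `regime_age`.
#' Day-9 A-type samples, excluded from the mixed models, are retained
#' here so the clustering display covers the full design.
#'
#' @param table a normalized [abundance_table()].
#' @return a `group_mean_matrix`: numeric matrix, metabolites in rows.
#' @export
group_means <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  meta <- table$meta
  groups <- unique(meta[c("regime", "age_days")])
  groups <- groups[order(groups$regime, groups$age_days), ]
  m <- sapply(seq_len(nrow(groups)), function(g) {
    idx <- meta$regime == groups$regime[g] &
      meta$age_days == groups$age_days[g]
    colMeans(table$values[idx, , drop = FALSE])
  })
  colnames(m) <- paste(groups$regime, groups$age_days, sep = "_")
  class(m) <- c("group_mean_matrix", class(m))
  m
}
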