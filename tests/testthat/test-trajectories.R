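planted_lmm_table <- function(nm = 20, offset = 3, seed = 5) {
  set.seed(seed)
  meta <- expand.grid(replicate_i = 1:4, age_days = c(21, 28, 35),
                      regime = c("A", "C"), stringsAsFactors = FALSE)
  meta$replicate <- paste0(meta$regime, meta$replicate_i)
  n <- nrow(meta)
  meta$sample_id <- sprintf("s%03d", seq_len(n))
  meta$history <- "long"; meta$batch <- 1; meta$n_pooled <- 50
  x <- matrix(stats::rnorm(n * nm, sd = 0.3), n, nm)
  colnames(x) <- sprintf("m%03d", seq_len(nm))
  x[meta$regime == "A", 1] <- x[meta$regime == "A", 1] + offset
  abundance_table(x, meta[c("sample_id", "regime", "history", "replicate",
                            "age_days", "batch", "n_pooled")],
                  stage = "normalized")
}

test_that("per-metabolite LMMs recover a planted selection effect", {
  tab <- planted_lmm_table()
  res <- fit_metabolite_lmms(tab, fdr = 0.01)
  expect_true(res$sig_selection[1])
  expect_lte(sum(res$sig_selection[-1]), 1)    # null columns stay quiet
  expect_true(all(res$converged))
  # q-values are monotone in p within each term
  o <- order(res$p_selection)
  expect_true(all(diff(res$q_selection[o]) >= -1e-12))
  # flags match the threshold definition exactly
  expect_equal(res$sig_age, !is.na(res$q_age) & res$q_age < 0.01)
  expect_error(fit_metabolite_lmms(subset_samples(tab,
    tab$meta$replicate %in% c("A1", "C1", "C2"))), "< 2 replicate")
})

test_that("LMM p-values match fixed-effects LRT when replicate variance is 0", {
  tab <- planted_lmm_table(nm = 5, offset = 1, seed = 7)
  res <- fit_metabolite_lmms(tab)
  d <- data.frame(sel = factor(tab$meta$regime),
                  age = factor(tab$meta$age_days))
  n <- nrow(d)
  for (j in 1:5) {
    y <- tab$values[, j]
    ll <- function(f) {
      r <- stats::resid(stats::lm(f, data = cbind(d, y = y)))
      -n / 2 * (log(2 * pi * mean(r^2)) + 1)
    }
    p_int <- stats::pchisq(2 * (ll(y ~ sel * age) - ll(y ~ sel + age)),
                           df = 2, lower.tail = FALSE)
    p_sel <- stats::pchisq(2 * (ll(y ~ sel + age) - ll(y ~ age)),
                           df = 1, lower.tail = FALSE)
    # replicate variance estimates at/near the boundary here, so the
    # mixed-model LRT should coincide with the fixed-effects one
    if (res$replicate_variance[j] < 1e-8) {
      expect_equal(res$p_interaction[j], p_int, tolerance = 1e-3)
      expect_equal(res$p_selection[j], p_sel, tolerance = 1e-3)
    }
  }
})

test_that("term overlap counts partition the significant set", {
  tab <- planted_lmm_table()
  res <- fit_metabolite_lmms(tab)
  oc <- term_overlap_counts(res)
  expect_equal(sum(oc$subsets), oc$total_significant)
  expect_equal(unname(oc$per_term["selection"]), sum(res$sig_selection))
  # fabricated flag patterns
  res$sig_selection <- rep(FALSE, nrow(res))
  res$sig_age <- rep(FALSE, nrow(res))
  res$sig_interaction <- rep(FALSE, nrow(res))
  oc0 <- term_overlap_counts(res)
  expect_true(all(unlist(oc0$subsets) == 0))
  expect_equal(oc0$total_significant, 0)
  res$sig_selection <- res$sig_age <- res$sig_interaction <-
    rep(TRUE, nrow(res))
  oc1 <- term_overlap_counts(res)
  expect_equal(unname(oc1$subsets["selection+age+interaction"]), nrow(res))
  expect_equal(sum(oc1$subsets), nrow(res))
})

test_that("group means reproduce the design cells", {
  norm <- shared_norm$norm
  gm <- group_means(norm)
  expect_equal(colnames(gm), c("A_9", "A_21", "A_28", "A_35",
                               "C_21", "C_28", "C_35", "C_70"))
  expect_equal(nrow(gm), ncol(norm$values))
  idx <- norm$meta$regime == "C" & norm$meta$age_days == 70
  expect_equal(unname(gm[, "C_70"]),
               unname(colMeans(norm$values[idx, ])))
  # duplicating samples leaves means unchanged
  dup <- abundance_table(rbind(norm$values, norm$values),
                         rbind(norm$meta, norm$meta), stage = "normalized")
  expect_equal(group_means(dup), gm)
  # one sample per group: the matrix is the sample itself
  one <- subset_samples(norm, !duplicated(norm$meta[c("regime", "age_days")]))
  gm1 <- group_means(one)
  expect_equal(unname(gm1[, "A_9"]),
               unname(one$values[one$meta$regime == "A" &
                                   one$meta$age_days == 9, ]))
})

test_that("the second-difference elbow finds an analytic kink", {
  # piecewise-linear WSS: slope -12 down to K = 7, slope -0.5 afterwards
  wss <- c(100 - 12 * (0:6), 28 - 0.5 * (1:12))
  expect_equal(elbow_from_wss(wss)$K, 7)
  # ties break toward smaller K: two equal kinks at 3 and 6
  wss2 <- c(60, 40, 20, 15, 10, 5, 4, 3, 2)
  d2 <- elbow_from_wss(wss2)$d2
  expect_equal(elbow_from_wss(wss2)$K,
               as.integer(names(d2)[which.max(d2)]))
  expect_error(elbow_from_wss(c(3, 2)), ">= 3")
})

test_that("k-means elbow recovers planted blobs and a monotone WSS", {
  pb <- planted_blobs(k = 4, per = 15, seed = 3)
  res <- choose_k_elbow(pb$x, k_max = 10, n_init = 10, seed = 1)
  expect_equal(res$K, 4)
  expect_true(all(diff(res$wss) <= 1e-6))
  expect_error(choose_k_elbow(pb$x, k_max = 2), ">= 3")
  expect_error(choose_k_elbow(pb$x[1:5, ], k_max = 10), "n_rows")
})

test_that("hierarchical clustering matches planted structure", {
  pb <- planted_blobs(k = 5, per = 8, seed = 4)
  sol <- hierarchical_cluster(pb$x, K = 5)
  expect_equal(length(unique(sol$assignments)), 5)
  # partition equals the planted blobs (up to label switching)
  expect_equal(length(unique(paste(sol$assignments, pb$truth))), 5)
  # identical rows co-cluster
  x <- rbind(a = c(0, 0), b = c(0, 0), c = c(10, 10))
  s2 <- hierarchical_cluster(x, K = 2)
  expect_equal(s2$assignments[["a"]], s2$assignments[["b"]])
  expect_false(s2$assignments[["a"]] == s2$assignments[["c"]])
  # row-order invariance as a set-of-sets
  perm <- sample(nrow(pb$x))
  sol2 <- hierarchical_cluster(pb$x[perm, ], K = 5)
  split1 <- unname(lapply(split(names(sol$assignments), sol$assignments),
                          sort))
  split2 <- unname(lapply(split(names(sol2$assignments), sol2$assignments),
                          sort))
  expect_setequal(vapply(split1, paste, "", collapse = ","),
                  vapply(split2, paste, "", collapse = ","))
  expect_error(hierarchical_cluster(rbind(x, a = c(1, 1)), K = 2),
               "duplicate")
})

make_aged_matrix <- function() {
  cols <- c("A_21", "A_28", "A_35", "C_21", "C_28", "C_35", "C_70")
  # cluster 1 rows: aged phenotype (C_70 looks like the A columns)
  aged <- matrix(rep(c(5, 5, 5, 0, 0, 0, 5), each = 4), 4, 7)
  # cluster 2 rows: C_70 tracks the young C profile
  young <- matrix(rep(c(5, 5, 5, 0, 0, 0, 0), each = 4), 4, 7)
  m <- rbind(aged, young) + matrix(stats::rnorm(56, sd = 0.05), 8, 7)
  colnames(m) <- cols
  rownames(m) <- sprintf("m%02d", 1:8)
  m
}

test_that("aged-phenotype flagging follows the distance rule", {
  set.seed(8)
  m <- make_aged_matrix()
  sol <- hierarchical_cluster(m, K = 2)
  flags <- flag_aged_phenotype(sol, m)
  aged_cluster <- unique(sol$assignments[sprintf("m%02d", 1:4)])
  expect_length(aged_cluster, 1)
  expect_true(flags[[as.character(aged_cluster)]])
  expect_false(flags[[as.character(setdiff(c(1, 2), aged_cluster))]])
  # exact tie (identical values everywhere) fails the strict inequality
  flat <- matrix(1, 4, 7,
                 dimnames = list(sprintf("f%d", 1:4), colnames(m)))
  solf <- list(assignments = stats::setNames(rep(1L, 4), rownames(flat)),
               K = 1)
  class(solf) <- "cluster_solution"
  expect_false(any(flag_aged_phenotype(solf, flat)))
  # C_70 exactly at the A centroid is flagged
  exact <- matrix(rep(c(2, 2, 2, 0, 0, 0, 2), each = 3), 3, 7,
                  dimnames = list(sprintf("e%d", 1:3), colnames(m)))
  sole <- list(assignments = stats::setNames(rep(1L, 3), rownames(exact)),
               K = 1)
  class(sole) <- "cluster_solution"
  expect_true(all(flag_aged_phenotype(sole, exact)))
  expect_error(flag_aged_phenotype(sole, exact[, -7, drop = FALSE]),
               "C_70")
})

test_that("BH adjustment agrees with the brute-force step-up", {
  set.seed(12)
  for (i in 1:10) {
    p <- stats::runif(50)^2
    expect_equal(stats::p.adjust(p, method = "BH"), brute_bh(p),
                 tolerance = 1e-12)
  }
})
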