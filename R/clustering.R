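#' Choose the number of clusters by the WSS second-difference elbow
#'
#' Runs K-means (Lloyd) for K = 1..`k_max` with `n_init` seeded restarts
#' each, keeping the minimum total within-cluster sum of squares (WSS) per
#' K, and picks the K with the largest discrete second difference
#' `d2(K) = [WSS(K+1) - WSS(K)] - [WSS(K) - WSS(K-1)]` over
#' K = 2..k_max-1 -- the "elbow" where adding clusters stops paying.
#' Ties break toward smaller K.
#'
#' @param matrix a [group_means()] matrix (rows are clustered).
#' @param k_max largest K to assess (>= 3, <= rows - 1).
#' @param n_init random restarts per K.
#' @param seed integer seed.
#' @param iter_max Lloyd iterations per restart.
#' @return a list with `K`, `wss` (length `k_max`), `d1`, `d2`.
#' @export
choose_k_elbow <- function(matrix, k_max = 200, n_init = 25, seed = 1,
                           iter_max = 50) {
  x <- unclass(matrix)
  if (k_max < 3) stop("k_max must be >= 3")
  if (k_max > nrow(x) - 1) stop("k_max must be <= n_rows - 1")
  set.seed(seed)
  wss <- numeric(k_max)
  wss[1] <- sum(sweep(x, 2, colMeans(x))^2)
  for (k in 2:k_max) {
    best <- Inf
    for (init in seq_len(n_init)) {
      km <- tryCatch(
        suppressWarnings(stats::kmeans(x, centers = k, nstart = 1,
                                       algorithm = "Lloyd",
                                       iter.max = iter_max)),
        error = function(e) NULL)
      if (!is.null(km) && km$tot.withinss < best) best <- km$tot.withinss
    }
    if (!is.finite(best)) {
      stop("k-means failed for all restarts at K = ", k,
           " (too few distinct rows?)")
    }
    wss[k] <- best
  }
  elbow <- elbow_from_wss(wss)
  c(list(K = elbow$K, wss = wss), elbow[c("d1", "d2")])
}

#' Second-difference elbow rule on a WSS curve
#'
#' The rule of [choose_k_elbow()] applied to an already-computed WSS
#' curve; exposed separately so the rule can be checked against curves
#' with a known kink.
#'
#' @param wss numeric vector, `wss[k]` the minimum WSS at K = k.
#' @return list with `K`, `d1` (first differences), `d2` (second
#'   differences, named by K).
#' @export
elbow_from_wss <- function(wss) {
  if (length(wss) < 3) stop("need WSS at >= 3 values of K")
  d1 <- diff(wss)                       # d1[k] = WSS(k+1) - WSS(k)
  d2 <- diff(d1)                        # indexed by K = 2..k_max-1
  names(d2) <- seq_along(d2) + 1
  K <- as.integer(names(d2)[which.max(d2)])  # which.max: first max = smaller K
  list(K = K, d1 = d1, d2 = d2)
}

#' Hierarchical clustering of the group-mean matrix
#'
#' Complete-linkage agglomeration on Euclidean distances for both rows
#' (metabolites) and columns (regime-age groups); row clusters come from
#' cutting the row dendrogram into K groups. Choosing K by the K-means
#' elbow but assigning clusters from the dendrogram mirrors common
#' heatmap practice.
#'
#' @param matrix a [group_means()] matrix with unique row names.
#' @param K number of row clusters (>= 2).
#' @return an object of class `cluster_solution`: list with `row_hclust`,
#'   `col_hclust`, `K`, `assignments` (named integer vector).
#' @export
hierarchical_cluster <- function(matrix, K) {
  x <- unclass(matrix)
  if (K < 2) stop("K must be >= 2")
  if (anyDuplicated(rownames(x))) stop("duplicate row identifiers")
  row_hc <- stats::hclust(stats::dist(x), method = "complete")
  col_hc <- stats::hclust(stats::dist(t(x)), method = "complete")
  assignments <- stats::cutree(row_hc, k = K)
  structure(list(row_hclust = row_hc, col_hclust = col_hc, K = K,
                 assignments = assignments),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat("<cluster_solution> ", length(x$assignments), " rows in ", x$K,
      " clusters (Euclidean, complete linkage)\n", sep = "")
  invisible(x)
}

#' Flag clusters showing the aged phenotype
#'
#' A cluster carries the "aged phenotype" when, restricted to its rows,
#' the oldest control samples (C, 70 d) resemble the accelerated-regime
#' samples more than the younger controls. Quantitatively, both must
#' hold with strict inequality: (a) the Euclidean distance from the C-70
#' column profile to the centroid of the A 21/28/35 columns is smaller
#' than to the centroid of the C 21/28/35 columns; and (b) averaged over
#' the A 21/28/35 columns, each A profile is closer to C-70 than to the
#' young-C centroid.
#'
#' @param solution a [hierarchical_cluster()] solution.
#' @param matrix the [group_means()] matrix it was built from; must have
#'   columns `A_21`, `A_28`, `A_35`, `C_21`, `C_28`, `C_35`, `C_70`.
#' @return named logical vector, one element per cluster.
#' @export
flag_aged_phenotype <- function(solution, matrix) {
  stopifnot(inherits(solution, "cluster_solution"))
  x <- unclass(matrix)
  a_cols <- c("A_21", "A_28", "A_35")
  cy_cols <- c("C_21", "C_28", "C_35")
  need <- c(a_cols, cy_cols, "C_70")
  if (!all(need %in% colnames(x))) {
    stop("matrix lacks required column(s): ",
         paste(setdiff(need, colnames(x)), collapse = ", "))
  }
  ks <- sort(unique(solution$assignments))
  flags <- vapply(ks, function(k) {
    rows <- names(solution$assignments)[solution$assignments == k]
    sub <- x[rows, , drop = FALSE]
    cent_a <- rowMeans(sub[, a_cols, drop = FALSE])
    cent_cy <- rowMeans(sub[, cy_cols, drop = FALSE])
    c70 <- sub[, "C_70"]
    dist2 <- function(u, v) sqrt(sum((u - v)^2))
    cond_a <- dist2(c70, cent_a) < dist2(c70, cent_cy)
    d_to_c70 <- mean(vapply(a_cols, function(cc)
      dist2(sub[, cc], c70), 1))
    d_to_cy <- mean(vapply(a_cols, function(cc)
      dist2(sub[, cc], cent_cy), 1))
    cond_b <- d_to_c70 < d_to_cy
    cond_a && cond_b
  }, logical(1))
  names(flags) <- ks
  flags
}
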