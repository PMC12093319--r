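#' Random-walk-with-restart diffusion scores over a metabolite network
#'
#' Stationary distribution of a random walk that, at each step, restarts
#' with probability `restart_prob` to a uniform distribution over the seed
#' metabolites and otherwise follows a (degree-normalized, weighted) edge.
#' Solved exactly as the linear system
#' `s = restart_prob * e + (1 - restart_prob) * t(P) s` on the largest
#' connected component; scores sum to 1. Pathway nodes adjacent (directly
#' or through intermediates) to the seeds accumulate mass, which is the
#' enrichment signal used by [permutation_enrichment()].
#'
#' @param network an igraph object with vertex attributes `name` and
#'   `type` (metabolite / intermediate / pathway), or a
#'   [simulate_network()] result.
#' @param seed_metabolites character vector of metabolite node names; at
#'   least one must map to the network.
#' @param restart_prob restart probability in (0, 1].
#' @return named numeric vector of scores over the nodes of the largest
#'   component, with attribute `dropped` listing any nodes outside it.
#' @export
diffusion_scores <- function(network, seed_metabolites,
                             restart_prob = 0.5) {
  g <- .as_graph(network)
  comp <- .largest_component(g)
  seeds <- intersect(seed_metabolites, igraph::V(comp$graph)$name)
  if (length(seeds) == 0) {
    stop("no seed metabolite maps to the network's largest component")
  }
  M <- .rwr_operator(comp$graph, restart_prob)
  e <- numeric(nrow(M))
  names(e) <- rownames(M)
  e[seeds] <- 1 / length(seeds)
  s <- drop(M %*% e)
  attr(s, "dropped") <- comp$dropped
  s
}

.as_graph <- function(network) {
  if (is.list(network) && !igraph::is_igraph(network) &&
      !is.null(network$graph)) {
    network <- network$graph
  }
  stopifnot(igraph::is_igraph(network))
  network
}

.largest_component <- function(g) {
  cmp <- igraph::components(g)
  keep <- which(cmp$membership == which.max(cmp$csize))
  dropped <- setdiff(igraph::V(g)$name, igraph::V(g)$name[keep])
  list(graph = igraph::induced_subgraph(g, keep), dropped = dropped)
}

# dense RWR fundamental operator: column j holds the stationary scores of
# a walk restarting at node j, so scores for any restart distribution e
# are M %*% e. Exact (direct solve); networks here are small.
.rwr_operator <- function(g, restart_prob) {
  if (restart_prob <= 0 || restart_prob > 1) {
    stop("restart_prob must be in (0, 1]")
  }
  A <- igraph::as_adjacency_matrix(g, attr = NULL, sparse = FALSE)
  deg <- rowSums(A)
  P <- A / deg                       # row-stochastic transition matrix
  n <- nrow(A)
  M <- restart_prob * solve(diag(n) - (1 - restart_prob) * t(P))
  rownames(M) <- colnames(M) <- igraph::V(g)$name
  M
}

#' Permutation enrichment of pathway nodes for a metabolite cluster
#'
#' Scores every pathway node by diffusion from the cluster's metabolites,
#' then compares each observed score with the scores obtained from
#' `n_perm` random draws of equally many metabolites from the annotated
#' background (all metabolite nodes in the network). The empirical
#' p-value uses the add-one correction
#' `p = (1 + #[perm >= obs]) / (1 + n_perm)`, so it can never be zero;
#' Benjamini-Hochberg FDR is computed across pathways, and pathways
#' passing `fdr` are ranked by p.
#'
#' @param network an igraph object or [simulate_network()] result.
#' @param cluster_metabolites metabolite names of the cluster under test.
#' @param n_perm number of permutations (>= 1; default 10000).
#' @param min_cluster minimum number of cluster metabolites mapping to
#'   the network (default 4); smaller clusters are skipped with a message
#'   and return `NULL`.
#' @param restart_prob restart probability of the diffusion.
#' @param fdr FDR threshold used for the `significant` flag.
#' @param seed integer seed for the permutation draws.
#' @return an object of class `enrichment_result` (data frame with
#'   columns `pathway`, `score`, `p_score`, `fdr`, `significant`,
#'   `rank`), or `NULL` for skipped clusters.
#' @export
permutation_enrichment <- function(network, cluster_metabolites,
                                   n_perm = 10000, min_cluster = 4,
                                   restart_prob = 0.5, fdr = 0.05,
                                   seed = 1) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  g <- .as_graph(network)
  comp <- .largest_component(g)
  g <- comp$graph
  type <- igraph::V(g)$type
  nodes <- igraph::V(g)$name
  background <- nodes[type == "metabolite"]
  pathways <- nodes[type == "pathway"]
  if (length(pathways) == 0) stop("network has no pathway nodes")
  cl <- intersect(cluster_metabolites, background)
  if (length(cl) < min_cluster) {
    message("cluster has ", length(cl), " mapped metabolite(s) < ",
            min_cluster, "; skipping")
    return(NULL)
  }
  M <- .rwr_operator(g, restart_prob)
  Mp <- M[pathways, background, drop = FALSE]
  obs <- rowMeans(Mp[, cl, drop = FALSE])
  set.seed(seed)
  k <- length(cl)
  exceed <- numeric(length(pathways))
  for (b in seq_len(n_perm)) {
    draw <- sample(background, k)
    perm <- rowMeans(Mp[, draw, drop = FALSE])
    exceed <- exceed + (perm >= obs)
  }
  p <- (1 + exceed) / (1 + n_perm)
  q <- stats::p.adjust(p, method = "BH")
  res <- data.frame(pathway = pathways, score = obs, p_score = p,
                    fdr = q, significant = q < fdr,
                    stringsAsFactors = FALSE)
  res <- res[order(res$p_score, -res$score), ]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  attr(res, "n_perm") <- n_perm
  attr(res, "cluster_size") <- k
  class(res) <- c("enrichment_result", "data.frame")
  res
}
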