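#' Simulate cohort death logs under a discrete Gompertz hazard
#'
#' Each replicate population is expanded into cohorts (two per replicate by
#' default, mirroring the caged assay design) of `cohort_size` flies.
#' Deaths on day d are binomial with hazard
#' `min(1, baseline * exp(growth * d))`; the assay runs until no flies
#' remain, so total deaths equal the cohort size.
#'
#' @param regime_params named list mapping each regime to
#'   `c(baseline, growth)`: the day-0 hazard and its exponential growth
#'   rate per day.
#' @param cohort_size flies per cohort (>= 1).
#' @param n_replicates replicate populations per regime.
#' @param cohorts_per_replicate cohorts per replicate population.
#' @param seed integer seed.
#' @return a `death_count_table`: data frame with columns `cohort`,
#'   `population`, `regime`, `day`, `deaths`.
#' @export
simulate_mortality <- function(regime_params, cohort_size,
                               n_replicates = 5, cohorts_per_replicate = 2,
                               seed = 1) {
  if (cohort_size < 1) stop("cohort_size must be >= 1")
  for (rg in names(regime_params)) {
    if (any(regime_params[[rg]] < 0)) stop("hazards must be >= 0")
  }
  set.seed(seed)
  out <- list()
  for (rg in names(regime_params)) {
    base <- regime_params[[rg]][1]
    growth <- regime_params[[rg]][2]
    for (rp in seq_len(n_replicates)) {
      for (ch in seq_len(cohorts_per_replicate)) {
        alive <- cohort_size
        day <- 0
        days <- integer(0); deaths <- integer(0)
        while (alive > 0) {
          day <- day + 1
          h <- min(1, base * exp(growth * day))
          d <- stats::rbinom(1, alive, h)
          if (day > 10000) { d <- alive }  # guard: hazard ~ 0
          days <- c(days, day); deaths <- c(deaths, d)
          alive <- alive - d
        }
        out[[length(out) + 1]] <- data.frame(
          cohort = sprintf("%s%d_c%d", rg, rp, ch),
          population = sprintf("%s%d", rg, rp),
          regime = rg, day = days, deaths = deaths,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("death_count_table", "data.frame")
  res
}

#' Simulate a metabolite-pathway network with planted memberships
#'
#' Builds a connected graph of metabolite and pathway nodes for testing
#' diffusion-based enrichment: each pathway node is linked to its planted
#' member metabolites; background metabolites are each linked to one random
#' pathway; with more than one pathway (or any background), a single
#' intermediate hub node bridges all pathway nodes so the graph is one
#' component. With one pathway and no background the result is a star.
#'
#' @param n_pathways number of pathway nodes (>= 1).
#' @param metabolites_per_pathway planted members per pathway (>= 1).
#' @param n_background additional metabolites not planted in any pathway.
#' @param seed integer seed.
#' @param metabolite_names optional character vector supplying metabolite
#'   node names (length >= pathways x members + background); defaults to
#'   `met_###`.
#' @return a list with `graph` (an [igraph::graph] with vertex attribute
#'   `type` in metabolite/intermediate/pathway) and `memberships` (named
#'   list: pathway -> planted metabolite names).
#' @export
simulate_network <- function(n_pathways, metabolites_per_pathway,
                             n_background, seed = 1,
                             metabolite_names = NULL) {
  if (n_pathways < 1 || metabolites_per_pathway < 1 || n_background < 0) {
    stop("counts must be >= 1 (background may be 0)")
  }
  set.seed(seed)
  n_met <- n_pathways * metabolites_per_pathway + n_background
  if (is.null(metabolite_names)) {
    mets <- sprintf("met_%03d", seq_len(n_met))
  } else {
    if (length(metabolite_names) < n_met) {
      stop("need at least ", n_met, " metabolite names")
    }
    mets <- metabolite_names[seq_len(n_met)]
  }
  pws <- sprintf("pw_%02d", seq_len(n_pathways))
  planted <- split(mets[seq_len(n_pathways * metabolites_per_pathway)],
                   rep(pws, each = metabolites_per_pathway))
  planted <- planted[pws]
  edges <- do.call(rbind, lapply(pws, function(p)
    cbind(p, planted[[p]])))
  bg <- mets[setdiff(seq_len(n_met),
                     seq_len(n_pathways * metabolites_per_pathway))]
  if (length(bg) > 0) {
    edges <- rbind(edges, cbind(sample(pws, length(bg), replace = TRUE), bg))
  }
  use_hub <- n_pathways > 1
  if (use_hub) edges <- rbind(edges, cbind("hub_01", pws))
  g <- igraph::graph_from_edgelist(as.matrix(edges), directed = FALSE)
  type <- ifelse(igraph::V(g)$name %in% pws, "pathway",
                 ifelse(igraph::V(g)$name %in% mets, "metabolite",
                        "intermediate"))
  g <- igraph::set_vertex_attr(g, "type", value = type)
  list(graph = g, memberships = planted)
}

#' Write / read a metabolite network as edge-list TSV
#'
#' Two plain-text files: `path` holds the two-column edge list and
#' `paste0(path, ".nodes")` a node-type sidecar (`node`, `type`).
#'
#' @param graph an igraph object with a `type` vertex attribute.
#' @param path edge-list file path.
#' @return `write_network` returns `path` invisibly; `read_network` the
#'   igraph object.
#' @export
write_network <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  utils::write.table(data.frame(from = el[, 1], to = el[, 2]), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  nodes <- data.frame(node = igraph::V(graph)$name,
                      type = igraph::V(graph)$type)
  utils::write.table(nodes, paste0(path, ".nodes"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  el <- utils::read.delim(path, stringsAsFactors = FALSE)
  nodes <- utils::read.delim(paste0(path, ".nodes"),
                             stringsAsFactors = FALSE)
  g <- igraph::graph_from_edgelist(as.matrix(el), directed = FALSE)
  idx <- match(igraph::V(g)$name, nodes$node)
  igraph::set_vertex_attr(g, "type", value = nodes$type[idx])
}
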