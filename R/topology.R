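#' Closed-form average degree and density from node/edge counts
#'
#' `averageDegree = 2E/N` and `density = 2E/(N(N-1))` — the identities any
#' simple undirected graph satisfies, usable directly on published
#' node/edge counts.
#'
#' @param nodes,edges Integer vectors (recycled together).
#' @return `data.frame(nodes, edges, averageDegree, density)`.
#' @export
#' @examples
#' topologyClosedForms(236, 2968)
topologyClosedForms <- function(nodes, edges) {
  stopifnot(all(nodes > 1))
  data.frame(nodes = nodes, edges = edges,
             averageDegree = 2 * edges / nodes,
             density = 2 * edges / (nodes * (nodes - 1)))
}

#' Topology panel of a co-occurrence network
#'
#' Computes the standard complexity panel: node and edge counts, average
#' degree, density, mean local clustering coefficient (0 for nodes of
#' degree < 2), average shortest path length and diameter on the largest
#' connected component (raw, plus the node-normalised variants used by the
#' sub-1 reporting convention), and modularity Q of the deterministic
#' greedy (CNM) partition.
#'
#' @param net A [CoOccurrenceNetwork-class] (or bare igraph).
#' @return A [TopologySummary-class]; an empty network yields an all-zero
#'   summary with a warning.
#' @export
summarizeTopology <- function(net) {
  g <- if (is(net, "CoOccurrenceNetwork")) net@graph else net
  grp <- if (is(net, "CoOccurrenceNetwork")) net@group else "NA"
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  if (n == 0) {
    warning("empty network: returning all-zero topology summary")
    return(new("TopologySummary", nodes = 0L, edges = 0L,
               averageDegree = 0, pathLength = 0, diameter = 0,
               pathLengthNormalized = 0, diameterNormalized = 0,
               density = 0, clusteringCoefficient = 0, modularity = 0,
               group = grp))
  }
  avgDeg <- 2 * e / n
  dens <- if (n > 1) 2 * e / (n * (n - 1)) else 0
  loc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  clust <- mean(loc)
  comp <- igraph::components(g)
  lcc <- igraph::induced_subgraph(g, which(comp$membership ==
                                             which.max(comp$csize)))
  pl <- if (igraph::vcount(lcc) > 1)
    igraph::mean_distance(lcc, directed = FALSE) else 0
  diam <- if (igraph::vcount(lcc) > 1)
    igraph::diameter(lcc, directed = FALSE, weights = NA) else 0
  mod <- if (e > 0) {
    cl <- igraph::cluster_fast_greedy(g, weights = NULL)
    igraph::modularity(cl)
  } else 0
  new("TopologySummary", nodes = as.integer(n), edges = as.integer(e),
      averageDegree = avgDeg, pathLength = pl, diameter = as.numeric(diam),
      pathLengthNormalized = pl / n, diameterNormalized = diam / n,
      density = dens, clusteringCoefficient = clust, modularity = mod,
      group = grp)
}

#' Side-by-side topology comparison across treatments
#'
#' @param summaries List of [TopologySummary-class] objects (>= 2).
#' @param control Group label (or index) used as baseline for the deltas.
#' @return `data.frame` with one row per network plus `delta*` columns
#'   (value minus control) for each numeric metric.
#' @export
compareTopology <- function(summaries, control = 1L) {
  if (length(summaries) < 2) stop("need >= 2 topology summaries to compare")
  df <- do.call(rbind, lapply(summaries, as.data.frame))
  if (is.character(control)) {
    control <- match(control, df$group)
    if (is.na(control)) stop("control group not found among summaries")
  }
  metrics <- setdiff(names(df), "group")
  for (mcol in metrics)
    df[[paste0("delta_", mcol)]] <- df[[mcol]] - df[[mcol]][control]
  df
}
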