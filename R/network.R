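#' Average node degree from node and edge counts
#'
#' `2 * nEdges / nNodes`: every edge contributes one degree to each endpoint.
#'
#' @param nNodes node count, at least 1.
#' @param nEdges edge count.
#' @return numeric scalar.
#' @examples
#' averageNodeDegree(56, 268)  # 9.5714...
#' @export
averageNodeDegree <- function(nNodes, nEdges) {
  if (nNodes < 1L) stop("graph has no nodes")
  if (nEdges < 0L) stop("negative edge count")
  2 * nEdges / nNodes
}

#' Average local clustering coefficient
#'
#' Mean over all nodes of the Watts-Strogatz local clustering coefficient,
#' `2 * triangles(v) / (deg(v) * (deg(v) - 1))`, with nodes of degree below 2
#' contributing 0 (they are included in the mean, not excluded). Edge weights
#' are ignored: clustering is computed on the unweighted graph after any
#' score thresholding.
#'
#' @param graph an undirected simple [igraph::igraph].
#' @return numeric scalar in `[0, 1]`.
#' @export
averageLocalClustering <- function(graph) {
  if (igraph::vcount(graph) == 0L) stop("empty graph")
  lc <- igraph::transitivity(graph, type = "local", isolates = "zero",
                             weights = NA)
  mean(lc)
}

#' Summarise an interaction network
#'
#' Node and edge counts, the average node degree and the average local
#' clustering coefficient, all computed on the same (simple, undirected)
#' graph.
#'
#' @param graph an undirected [igraph::igraph].
#' @return a [GraphSummary-class].
#' @export
graphSummary <- function(graph) {
  n <- igraph::vcount(graph)
  if (n == 0L) stop("empty graph")
  if (any(igraph::which_loop(graph)) || any(igraph::which_multiple(graph)))
    stop("graph must be simple (no loops or duplicate edges)")
  m <- igraph::ecount(graph)
  new("GraphSummary", nNodes = as.integer(n), nEdges = as.integer(m),
      avgNodeDegree = averageNodeDegree(n, m),
      avgLocalClustering = averageLocalClustering(graph))
}
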