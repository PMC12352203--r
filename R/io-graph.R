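#' Read a STRING-style weighted edge list
#'
#' Expects a tab-separated file with columns `node1`, `node2` and
#' `combined_score` on STRING's 0-1000 integer scale. Edges are undirected;
#' self-loop rows are dropped with a warning; duplicate pairs collapse to the
#' maximum weight; only edges with weight at least `minScore * 1000` are kept
#' (so the conventional 0-1 confidence, e.g. highest confidence 0.900, can be
#' given directly). Nodes are the endpoints of the retained edges.
#'
#' @param path TSV file.
#' @param minScore confidence threshold on the 0-1 scale (default 0.9).
#' @return an undirected [igraph::igraph] with a `weight` edge attribute.
#' @export
readStringEdges <- function(path, minScore = 0.9) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(df) == 0L)
    return(igraph::make_empty_graph(0, directed = FALSE))
  need <- c("node1", "node2", "combined_score")
  if (!all(need %in% names(df)))
    stop("edge list needs columns ", paste(need, collapse = ", "))
  w <- as.numeric(df$combined_score)
  if (any(is.na(w))) stop("malformed combined_score value")
  loop <- df$node1 == df$node2
  if (any(loop)) {
    warning(sum(loop), " self-loop row(s) dropped")
    df <- df[!loop, , drop = FALSE]; w <- w[!loop]
  }
  keep <- w >= minScore * 1000
  df <- df[keep, , drop = FALSE]; w <- w[keep]
  if (nrow(df) == 0L)
    return(igraph::make_empty_graph(0, directed = FALSE))
  a <- pmin(df$node1, df$node2)
  b <- pmax(df$node1, df$node2)
  key <- paste(a, b, sep = "\r")
  wMax <- tapply(w, key, max)
  pairs <- do.call(rbind, strsplit(names(wMax), "\r", fixed = TRUE))
  g <- igraph::graph_from_data_frame(
    data.frame(from = pairs[, 1], to = pairs[, 2],
               weight = as.numeric(wMax)),
    directed = FALSE)
  g
}

#' Write a weighted graph as a STRING-style edge list
#'
#' @param graph an undirected [igraph::igraph] with a `weight` edge attribute
#'   on the 0-1000 scale.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeStringEdges <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  w <- igraph::E(graph)$weight
  if (is.null(w)) w <- rep(1000, nrow(el))
  utils::write.table(data.frame(node1 = el[, 1], node2 = el[, 2],
                                combined_score = w),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
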