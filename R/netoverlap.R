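#' Build the pathway-overlap network
#'
#' Each pathway is a node; an edge joins two pathways whose shared genes make
#' up at least \code{overlap_fraction} of their combined (union) gene count
#' (Jaccard index >= 0.05 under the defaults; \code{denominator = "min"}
#' divides by the smaller set instead). After edge construction, a single
#' pass removes every node connected to fewer than \code{min_network_degree}
#' other pathways, together with its incident edges; with
#' \code{iterate_pruning = TRUE} the pass repeats until no node falls below
#' the threshold.
#'
#' @param pathways A \code{\link{pathway_collection}}.
#' @param config An \code{\link{analysis_config}}.
#' @param denominator \code{"union"} (default) or \code{"min"}.
#' @param iterate_pruning Repeat pruning to a fixed point.
#' @param selected Optional pathway IDs to flag (e.g. the shared-pathway set).
#' @return A list of class \code{overlap_network}: \code{graph} (igraph),
#'   \code{nodes}, \code{edges} (two-column data.frame), \code{selected}.
#' @export
build_overlap_network <- function(pathways, config = analysis_config(),
                                  denominator = c("union", "min"),
                                  iterate_pruning = FALSE,
                                  selected = character()) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(pathways, "pathway_collection"))
  sets <- pathways$sets
  if (length(sets) < 2) stop("need at least 2 pathways")
  ids <- names(sets)
  universe <- unique(unlist(sets, use.names = FALSE))
  M <- matrix(0L, nrow = length(ids), ncol = length(universe),
              dimnames = list(ids, universe))
  for (id in ids) M[id, sets[[id]]] <- 1L
  inter <- tcrossprod(M)
  sizes <- lengths(sets)
  denom <- if (denominator == "union") outer(sizes, sizes, `+`) - inter
           else outer(sizes, sizes, pmin)
  frac <- inter / denom
  adj <- frac >= config$overlap_fraction
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  repeat {
    low <- igraph::V(g)[igraph::degree(g) < config$min_network_degree]
    if (!length(low)) break
    g <- igraph::delete_vertices(g, low)
    if (!iterate_pruning) break
  }
  if (igraph::vcount(g) == 0)
    stop("overlap network empty after pruning: no pathway kept >= ",
         config$min_network_degree, " neighbours (", sum(adj) / 2,
         " edges before pruning among ", length(ids), " pathways)")
  el <- igraph::as_edgelist(g)
  structure(
    list(graph = g,
         nodes = igraph::V(g)$name,
         edges = data.frame(from = el[, 1], to = el[, 2],
                            stringsAsFactors = FALSE),
         selected = intersect(selected, igraph::V(g)$name)),
    class = "overlap_network")
}

#' @export
print.overlap_network <- function(x, ...) {
  cat(sprintf("overlap_network: %d nodes, %d edges (%d selected)\n",
              length(x$nodes), nrow(x$edges), length(x$selected)))
  invisible(x)
}

#' Degree and betweenness centrality per node
#'
#' Degree is the incident-edge count; betweenness is the number of shortest
#' paths between other node pairs passing through the node (unweighted,
#' undirected, shortest-path ties split fractionally, no pair
#' normalization).
#'
#' @param network An \code{\link{build_overlap_network}} result.
#' @return A data.frame with columns \code{pathway_id}, \code{degree},
#'   \code{betweenness}.
#' @export
node_centralities <- function(network) {
  stopifnot(inherits(network, "overlap_network"))
  g <- network$graph
  if (igraph::vcount(g) == 0) stop("empty network")
  data.frame(pathway_id = igraph::V(g)$name,
             degree = unname(igraph::degree(g)),
             betweenness = unname(igraph::betweenness(g, directed = FALSE,
                                                      normalized = FALSE)),
             stringsAsFactors = FALSE)
}

#' Degree distribution of the network
#'
#' @param network An \code{\link{build_overlap_network}} result.
#' @return Named numeric vector: relative frequency per observed degree
#'   value (sums to 1).
#' @export
degree_distribution <- function(network) {
  stopifnot(inherits(network, "overlap_network"))
  d <- igraph::degree(network$graph)
  if (!length(d)) stop("empty network")
  tab <- table(d)
  stats::setNames(as.numeric(tab) / sum(tab), names(tab))
}

#' Compare degrees of selected pathways against the rest
#'
#' Summarizes the degree of the selected (flagged) nodes versus all other
#' nodes and reports a rank-based comparison (two-sided Wilcoxon rank-sum).
#'
#' @param stats_df A \code{\link{node_centralities}} data.frame.
#' @param selected Character vector of selected pathway IDs; must be a
#'   non-empty proper subset of the network's nodes.
#' @return A list: \code{median_selected}, \code{median_other},
#'   \code{difference} (selected minus other), \code{wilcox_p}.
#' @export
compare_selected_degree <- function(stats_df, selected) {
  sel <- stats_df$pathway_id %in% selected
  if (!any(sel) || all(sel))
    stop("selected set must be a non-empty proper subset of the nodes")
  d_sel <- stats_df$degree[sel]
  d_oth <- stats_df$degree[!sel]
  wt <- suppressWarnings(stats::wilcox.test(d_sel, d_oth))
  list(median_selected = stats::median(d_sel),
       median_other = stats::median(d_oth),
       difference = stats::median(d_sel) - stats::median(d_oth),
       wilcox_p = wt$p.value)
}

#' Write the network edge list
#'
#' @param network An \code{\link{build_overlap_network}} result.
#' @param path Output path (tab-delimited pathway-ID pairs).
#' @return \code{path}, invisibly.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "overlap_network"))
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
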