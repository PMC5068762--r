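#' Largest connected component of a network
#'
#' Ties in component size break toward the component containing the
#' lexicographically smallest node id, so the result is deterministic.
#'
#' @param net an [igraph::igraph] object.
#' @return the induced subgraph on the largest component.
#' @export
largest_component <- function(net) {
  if (igraph::vcount(net) == 0L) stop("empty graph")
  comp <- igraph::components(net)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    firsts <- vapply(best, function(k) {
      min(igraph::V(net)$name[comp$membership == k])
    }, "")
    best <- best[order(firsts)][1L]
  }
  igraph::induced_subgraph(net, which(comp$membership == best))
}

#' Per-node topology statistics of a connected undirected network
#'
#' For every node of a connected, simple, unweighted graph computes:
#' \describe{
#'   \item{degree}{number of neighbours.}
#'   \item{stress}{total number of shortest paths between other node pairs
#'     passing through the node.}
#'   \item{betweenness}{the pair-averaged proportion of shortest paths
#'     through the node, normalized by `(n - 1)(n - 2)/2` so values lie in
#'     `[0, 1]` (1 for the centre of a star).}
#'   \item{eccentricity}{the largest shortest-path distance to any node.}
#'   \item{avg_shortest_path}{mean shortest-path distance to all other
#'     nodes.}
#' }
#' Distances are unweighted hops; directed input is symmetrized.
#'
#' @param net a connected [igraph::igraph]; run [largest_component()]
#'   first if the network may be disconnected.
#' @return data frame with one row per node (`node` column plus the five
#'   statistics).
#' @export
node_stats <- function(net) {
  if (igraph::vcount(net) == 0L) stop("empty graph")
  if (igraph::is_directed(net)) {
    net <- igraph::as_undirected(net, mode = "collapse")
  }
  net <- igraph::simplify(net)
  if (!igraph::is_connected(net)) {
    stop("graph is disconnected; run node_stats(largest_component(net))")
  }
  nodes <- igraph::V(net)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(igraph::vcount(net)))
  el <- igraph::as_edgelist(net, names = FALSE)
  storage.mode(el) <- "integer"
  out <- .node_stats_cpp(igraph::vcount(net), el - 1L)
  out <- cbind(data.frame(node = nodes, stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}

#' Compare a node group against the rest on one topology statistic
#'
#' Two-sided Wilcoxon rank-sum test (normal approximation with tie and
#' continuity correction) of the chosen statistic between a gene group
#' (e.g. broadest-peak-associated genes) and all remaining nodes, with
#' group/rest medians and their ratio.
#'
#' @param stats a [node_stats()] data frame.
#' @param group character vector of node ids; must be a non-empty proper
#'   subset of the nodes.
#' @param metric one of `"degree"`, `"stress"`, `"betweenness"`,
#'   `"eccentricity"`, `"avg_shortest_path"`.
#' @return list with `metric`, `n_group`, `n_rest`, `median_group`,
#'   `median_rest`, `ratio` (group/rest), `statistic` (the rank-sum W) and
#'   `p_value`.
#' @export
compare_groups <- function(stats, group,
                           metric = c("degree", "stress", "betweenness",
                                      "eccentricity", "avg_shortest_path")) {
  metric <- match.arg(metric)
  in_group <- stats$node %in% group
  if (!any(in_group)) stop("group is empty (no group id matches a node)")
  if (all(in_group)) stop("group covers every node; nothing to compare")
  x <- stats[[metric]][in_group]
  y <- stats[[metric]][!in_group]
  if (length(unique(c(x, y))) == 1L) {
    # fully tied metric (e.g. degree on a vertex-transitive graph): the
    # rank-sum statistic has zero variance and there is nothing to detect
    wt <- list(statistic = c(W = length(x) * length(y) / 2), p.value = 1)
  } else {
    wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided",
                                       exact = FALSE, correct = TRUE))
  }
  mg <- median(x); mr <- median(y)
  list(metric = metric, n_group = length(x), n_rest = length(y),
       median_group = mg, median_rest = mr,
       ratio = if (mr != 0) mg / mr else if (mg > 0) Inf else NaN,
       statistic = unname(wt$statistic), p_value = wt$p.value)
}
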