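#' Construct and validate a river network
#'
#' A river network is a directed in-tree of subcatchment nodes: every node
#' drains to exactly one downstream neighbour, except a single outlet node
#' with no downstream edge. Edges are stored upstream -> downstream and carry
#' the instream length between the two subcatchment outlets; nodes carry the
#' local (not accumulated) subcatchment area.
#'
#' @param nodes data frame with columns `node_id`, `local_area_km2` and
#'   optionally `x`, `y` coordinates.
#' @param edges data frame with columns `from_node` (upstream), `to_node`
#'   (downstream) and `length_km` (> 0).
#'
#' @return An object of class `river_network`: a list with elements `nodes`,
#'   `edges`, `outlet` (node id), `down` (named vector mapping each node id to
#'   its downstream neighbour, `NA` at the outlet) and `up` (named list of
#'   upstream neighbour ids).
#'
#' @details Validation enforces the in-tree topology: unique node ids, edges
#'   referencing declared nodes only, strictly positive lengths, non-negative
#'   local areas, at most one downstream edge per node, exactly one outlet,
#'   and acyclicity/connectedness (every node's downstream walk must reach
#'   the outlet). Each violation raises a distinct error naming the offending
#'   node or edge.
#' @export
river_network <- function(nodes, edges) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  req_n <- c("node_id", "local_area_km2")
  req_e <- c("from_node", "to_node", "length_km")
  if (!all(req_n %in% names(nodes)))
    stop("node table must have columns: ", paste(req_n, collapse = ", "))
  if (!all(req_e %in% names(edges)))
    stop("edge table must have columns: ", paste(req_e, collapse = ", "))
  nodes$node_id <- as.character(nodes$node_id)
  edges$from_node <- as.character(edges$from_node)
  edges$to_node <- as.character(edges$to_node)

  if (anyDuplicated(nodes$node_id))
    stop("duplicate node id: ",
         paste(unique(nodes$node_id[duplicated(nodes$node_id)]), collapse = ", "))
  ids <- nodes$node_id
  unknown <- setdiff(c(edges$from_node, edges$to_node), ids)
  if (length(unknown))
    stop("edge references unknown node id: ", paste(unknown, collapse = ", "))
  if (any(!is.finite(edges$length_km) | edges$length_km <= 0)) {
    bad <- which(!is.finite(edges$length_km) | edges$length_km <= 0)[1L]
    stop("non-positive edge length on edge ", edges$from_node[bad], " -> ",
         edges$to_node[bad])
  }
  if (any(!is.finite(nodes$local_area_km2) | nodes$local_area_km2 < 0))
    stop("negative or missing local area at node: ",
         paste(nodes$node_id[!is.finite(nodes$local_area_km2) |
                               nodes$local_area_km2 < 0], collapse = ", "))
  dup_out <- edges$from_node[duplicated(edges$from_node)]
  if (length(dup_out))
    stop("node with more than one downstream edge: ",
         paste(unique(dup_out), collapse = ", "))

  down <- stats::setNames(rep(NA_character_, length(ids)), ids)
  down[edges$from_node] <- edges$to_node
  outlets <- ids[is.na(down)]
  if (length(outlets) == 0L)
    stop("cycle detected: no outlet node (every node has a downstream edge)")
  if (length(outlets) > 1L)
    stop("more than one outlet node: ", paste(outlets, collapse = ", "))

  # every node's downstream walk must terminate at the outlet (acyclic and
  # connected); a revisited node flags a cycle
  depth <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  depth[outlets] <- 0L
  for (v in ids) {
    if (!is.na(depth[v])) next
    path <- character(0)
    w <- v
    while (is.na(depth[w])) {
      if (w %in% path)
        stop("cycle detected involving node ", w)
      path <- c(path, w)
      w <- down[[w]]
    }
    base <- depth[[w]]
    depth[path] <- base + rev(seq_along(path))
  }

  up <- split(edges$from_node, factor(edges$to_node, levels = ids))
  names(up) <- ids
  structure(list(nodes = nodes, edges = edges, outlet = outlets,
                 down = down, up = up),
            class = "river_network")
}

#' @export
print.river_network <- function(x, ...) {
  cat("river_network:", nrow(x$nodes), "nodes,", nrow(x$edges),
      "edges; outlet:", x$outlet, "\n")
  cat("  total local area:", sum(x$nodes$local_area_km2), "km2;",
      "total instream length:", sum(x$edges$length_km), "km\n")
  invisible(x)
}

#' Read a river network from node and edge tables
#'
#' @param node_table_path TSV with columns `node_id`, `local_area_km2`,
#'   optional `x`, `y`.
#' @param edge_table_path TSV with columns `from_node` (upstream), `to_node`
#'   (downstream), `length_km`.
#' @return A validated [river_network()].
#' @export
read_network <- function(node_table_path, edge_table_path) {
  nodes <- utils::read.delim(node_table_path, stringsAsFactors = FALSE,
                             colClasses = c(node_id = "character"))
  edges <- utils::read.delim(edge_table_path, stringsAsFactors = FALSE,
                             colClasses = c(from_node = "character",
                                            to_node = "character"))
  river_network(nodes, edges)
}

#' Write a river network to node and edge TSV tables
#'
#' @param net a [river_network()].
#' @param node_table_path,edge_table_path output paths.
#' @export
write_network <- function(net, node_table_path, edge_table_path) {
  utils::write.table(net$nodes, node_table_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(net$edges, edge_table_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(net)
}

#' Convert a river network to an igraph graph
#'
#' Edges are directed upstream -> downstream (flow orientation) and weighted
#' by instream length (km).
#' @param net a [river_network()].
#' @param directed keep the flow orientation (default) or collapse to an
#'   undirected graph.
#' @return an `igraph` graph with vertex attributes `name`, `local_area_km2`
#'   and edge attribute `weight`.
#' @export
as_igraph <- function(net, directed = TRUE) {
  stopifnot(inherits(net, "river_network"))
  g <- igraph::graph_from_data_frame(
    data.frame(from = net$edges$from_node, to = net$edges$to_node,
               weight = net$edges$length_km, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = net$nodes$node_id,
                          local_area_km2 = net$nodes$local_area_km2,
                          stringsAsFactors = FALSE))
  if (!directed) g <- igraph::as_undirected(g, mode = "each")
  g
}

#' Instream distance of every node to the outlet
#'
#' Distance (km) along the unique downstream path to the outlet node,
#' summing edge lengths. Zero at the outlet.
#' @param net a [river_network()].
#' @return named numeric vector over nodes (km).
#' @export
upstream_distances <- function(net) {
  stopifnot(inherits(net, "river_network"))
  ids <- net$nodes$node_id
  len <- stats::setNames(rep(NA_real_, length(ids)), ids)
  el <- stats::setNames(net$edges$length_km, net$edges$from_node)
  dist <- stats::setNames(rep(NA_real_, length(ids)), ids)
  dist[net$outlet] <- 0
  for (v in ids) {
    if (!is.na(dist[v])) next
    path <- character(0)
    w <- v
    while (is.na(dist[w])) {
      path <- c(path, w)
      w <- net$down[[w]]
    }
    acc <- dist[[w]]
    for (u in rev(path)) {
      acc <- acc + el[[u]]
      dist[u] <- acc
    }
  }
  dist
}

#' Accumulated (total upstream) catchment area
#'
#' For every node, the sum of its local subcatchment area and the local areas
#' of all nodes upstream of it. The outlet's value equals the total area of
#' the network.
#' @param net a [river_network()].
#' @return named numeric vector over nodes (km^2).
#' @export
catchment_accumulation <- function(net) {
  stopifnot(inherits(net, "river_network"))
  ids <- net$nodes$node_id
  acc <- stats::setNames(net$nodes$local_area_km2, ids)
  # process nodes from the most upstream downwards (decreasing depth)
  depth <- upstream_distances(net)
  for (v in ids[order(depth, decreasing = TRUE)]) {
    dn <- net$down[[v]]
    if (!is.na(dn)) acc[dn] <- acc[dn] + acc[v]
  }
  acc
}

#' Betweenness centrality of network nodes
#'
#' Number of weighted shortest paths between node pairs passing through each
#' node (endpoints excluded), with instream lengths as edge weights. In
#' directed mode paths follow the downstream flow orientation and ordered
#' pairs are counted; in undirected mode orientation is ignored and each
#' unordered pair is counted once. Values are raw (unnormalized) path counts.
#' @param net a [river_network()].
#' @param directed respect flow orientation.
#' @return named numeric vector over nodes.
#' @export
net_betweenness <- function(net, directed = FALSE) {
  g <- as_igraph(net, directed = directed)
  b <- igraph::betweenness(g, directed = directed,
                           weights = igraph::E(g)$weight)
  b[net$nodes$node_id]
}

#' Closeness centrality of network nodes
#'
#' The reciprocal of the sum of instream distances between a node and all
#' other nodes. In directed mode distances follow the downstream orientation
#' and unreachable pairs are excluded from the sum (on an in-tree only the
#' downstream path of a node is reachable); the number of reachable
#' neighbours is recorded in the `"n_reachable"` attribute. A node reaching
#' no other node gets `NA`.
#' @param net a [river_network()].
#' @param directed respect flow orientation.
#' @return named numeric vector over nodes with attribute `n_reachable`.
#' @export
net_closeness <- function(net, directed = FALSE) {
  g <- as_igraph(net, directed = TRUE)
  D <- igraph::distances(g, mode = if (directed) "out" else "all",
                         weights = igraph::E(g)$weight)
  D <- D[net$nodes$node_id, net$nodes$node_id, drop = FALSE]
  diag(D) <- NA
  reach <- rowSums(is.finite(D), na.rm = TRUE)
  s <- rowSums(ifelse(is.finite(D), D, 0), na.rm = TRUE)
  cl <- ifelse(reach > 0, 1 / s, NA_real_)
  names(cl) <- net$nodes$node_id
  attr(cl, "n_reachable") <- stats::setNames(reach, net$nodes$node_id)
  cl
}

#' Standardize a closeness map to the unit interval
#'
#' Applies `(c - min c) / (max c - min c)` over the node set, so the least
#' central node maps to 0 and the most central one to 1. `NA` entries are
#' ignored for the range and preserved in the output.
#' @param closeness named numeric vector, e.g. from [net_closeness()].
#' @return named numeric vector in `[0, 1]`.
#' @export
standardize_closeness <- function(closeness) {
  r <- range(closeness, na.rm = TRUE)
  if (!is.finite(r[1]) || r[2] - r[1] <= 0)
    stop("degenerate closeness spread: all values equal, cannot standardize")
  out <- (closeness - r[1]) / (r[2] - r[1])
  attr(out, "n_reachable") <- NULL
  out
}

#' Undirected degree of network nodes
#' @param net a [river_network()].
#' @return named integer vector (number of incident edges).
#' @export
net_degree <- function(net) {
  stopifnot(inherits(net, "river_network"))
  tab <- table(factor(c(net$edges$from_node, net$edges$to_node),
                      levels = net$nodes$node_id))
  stats::setNames(as.integer(tab), net$nodes$node_id)
}

#' Pairwise instream distance matrix
#'
#' Along-network (undirected tree path) distance in km for every pair of the
#' requested nodes; symmetric with zero diagonal.
#' @param net a [river_network()].
#' @param subset node ids to include (default: all nodes).
#' @return symmetric numeric matrix with dimnames set to node ids.
#' @export
instream_distance_matrix <- function(net, subset = NULL) {
  stopifnot(inherits(net, "river_network"))
  if (is.null(subset)) subset <- net$nodes$node_id
  subset <- as.character(subset)
  unknown <- setdiff(subset, net$nodes$node_id)
  if (length(unknown))
    stop("unknown node id: ", paste(unknown, collapse = ", "))
  g <- as_igraph(net, directed = TRUE)
  D <- igraph::distances(g, v = subset, to = subset, mode = "all",
                         weights = igraph::E(g)$weight)
  D[subset, subset, drop = FALSE]
}

#' All node metrics as a tidy table
#'
#' Computes the per-node predictor set used in network-genetics regressions:
#' upstream distance from the outlet, total upstream catchment area, directed
#' and undirected betweenness, directed and undirected closeness, closeness
#' standardized to `[0, 1]` (from the undirected variant), and degree.
#' @param net a [river_network()].
#' @return data frame with one row per node.
#' @export
node_metrics <- function(net) {
  ids <- net$nodes$node_id
  cl_u <- net_closeness(net, directed = FALSE)
  cl_d <- net_closeness(net, directed = TRUE)
  data.frame(
    node_id = ids,
    local_area_km2 = net$nodes$local_area_km2,
    upstream_distance = as.numeric(upstream_distances(net)[ids]),
    catchment_area = as.numeric(catchment_accumulation(net)[ids]),
    betweenness_directed = as.numeric(net_betweenness(net, TRUE)[ids]),
    betweenness_undirected = as.numeric(net_betweenness(net, FALSE)[ids]),
    closeness_directed = as.numeric(cl_d[ids]),
    closeness_undirected = as.numeric(cl_u[ids]),
    closeness_std = as.numeric(standardize_closeness(cl_u)[ids]),
    degree = as.integer(net_degree(net)[ids]),
    stringsAsFactors = FALSE)
}
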