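#' Attributed social graph
#'
#' A `social_graph` is an undirected, unweighted graph over a fixed, ordered
#' set of entity identifiers, stored as a symmetric binary adjacency matrix.
#' The node order is significant: it is the tie-breaking order used by the
#' clustering algorithm, and by convention equals the row order of the
#' node-attribute table the graph accompanies.
#'
#' @param adjacency symmetric 0/1 matrix with zero diagonal.
#' @param node_ids character vector of unique node identifiers, one per
#'   matrix row, in tie-breaking order.
#' @return An object of class `social_graph`: a list with elements
#'   `ids` (character) and `adj` (integer matrix with `ids` as dimnames).
#' @examples
#' g <- social_graph(matrix(c(0, 1, 1, 0), 2, 2), c("a", "b"))
#' n_nodes(g)
#' @export
social_graph <- function(adjacency, node_ids) {
  node_ids <- as.character(node_ids)
  if (anyDuplicated(node_ids)) {
    stop_input("duplicate node id: %s",
               paste(unique(node_ids[duplicated(node_ids)]), collapse = ", "))
  }
  adjacency <- as.matrix(adjacency)
  n <- length(node_ids)
  if (!is.numeric(adjacency) || nrow(adjacency) != n || ncol(adjacency) != n) {
    stop_input("adjacency must be a %d x %d numeric matrix", n, n)
  }
  if (!all(adjacency %in% c(0, 1))) {
    stop_input("adjacency entries must be 0 or 1")
  }
  if (!isTRUE(all.equal(adjacency, t(adjacency), check.attributes = FALSE))) {
    stop_input("adjacency must be symmetric (graph is undirected)")
  }
  if (any(diag(adjacency) != 0)) {
    stop_input("adjacency diagonal must be zero (no self-loops)")
  }
  storage.mode(adjacency) <- "integer"
  dimnames(adjacency) <- list(node_ids, node_ids)
  structure(list(ids = node_ids, adj = adjacency), class = "social_graph")
}

#' Build a social graph from an edge list
#'
#' Duplicate edges (in either orientation) are collapsed; self-loops are
#' dropped with a warning. Nodes listed in `node_ids` but absent from
#' `edges` become isolated nodes.
#'
#' @param edges a two-column matrix or data frame of id pairs (character),
#'   or a zero-row object for an edgeless graph.
#' @param node_ids ordered character vector of all node ids.
#' @return A [social_graph()].
#' @examples
#' g <- social_graph_from_edges(cbind("A", "B"), c("A", "B", "C"))
#' @export
social_graph_from_edges <- function(edges, node_ids) {
  node_ids <- as.character(node_ids)
  n <- length(node_ids)
  adj <- matrix(0L, n, n)
  if (!is.null(edges) && NROW(edges) > 0) {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2) stop_input("edge list must have exactly two columns")
    from <- as.character(edges[, 1])
    to <- as.character(edges[, 2])
    i <- match(from, node_ids)
    j <- match(to, node_ids)
    if (anyNA(i) || anyNA(j)) {
      bad <- unique(c(from[is.na(i)], to[is.na(j)]))
      stop_input("edge references unknown node id: %s",
                 paste(bad, collapse = ", "))
    }
    loops <- i == j
    if (any(loops)) {
      warning(sprintf("dropping %d self-loop(s) on: %s", sum(loops),
                      paste(unique(from[loops]), collapse = ", ")))
      i <- i[!loops]
      j <- j[!loops]
    }
    adj[cbind(i, j)] <- 1L
    adj[cbind(j, i)] <- 1L
  }
  social_graph(adj, node_ids)
}

#' @export
print.social_graph <- function(x, ...) {
  cat(sprintf("<social_graph> %d nodes, %d edges\n",
              n_nodes(x), n_edges(x)))
  invisible(x)
}

#' Number of nodes / edges of a social graph
#' @param g a [social_graph()].
#' @return An integer count.
#' @export
n_nodes <- function(g) length(g$ids)

#' @rdname n_nodes
#' @export
n_edges <- function(g) sum(g$adj) %/% 2L

#' Node degrees, in input order
#' @param g a [social_graph()].
#' @return Named integer vector of degrees.
#' @export
node_degrees <- function(g) {
  d <- rowSums(g$adj)
  names(d) <- g$ids
  d
}

#' Extract the edge list of a social graph
#' @param g a [social_graph()].
#' @return A two-column character matrix (`from`, `to`), one row per
#'   undirected edge, with `from` earlier in node order than `to`.
#' @export
edge_list <- function(g) {
  idx <- which(upper.tri(g$adj) & g$adj == 1L, arr.ind = TRUE)
  cbind(from = g$ids[idx[, 1]], to = g$ids[idx[, 2]])
}

as_igraph <- function(g) {
  igraph::graph_from_adjacency_matrix(g$adj, mode = "undirected")
}

check_ids <- function(g, ids) {
  idx <- match(as.character(ids), g$ids)
  if (anyNA(idx)) {
    stop_input("unknown node id: %s",
               paste(as.character(ids)[is.na(idx)], collapse = ", "))
  }
  idx
}

#' Shortest-path length between two nodes, in edges
#'
#' Breadth-first search on the unweighted graph: the minimum number of
#' edges on any path between `vi` and `vj`; 0 when `vi == vj`; `Inf` when
#' the two nodes lie in different connected components.
#'
#' @param g a [social_graph()].
#' @param vi,vj node ids.
#' @return Non-negative number of edges, or `Inf`.
#' @export
shortest_path_edges <- function(g, vi, vj) {
  i <- check_ids(g, vi)
  j <- check_ids(g, vj)
  as.numeric(igraph::distances(as_igraph(g), v = i, to = j)[1, 1])
}

#' Normalized shortest-path distance between two nodes
#'
#' With `L` the shortest-path length in edges, the distance is
#' `L / (L + 1)` — equivalently `d / mn` with `d = L` the edge count and
#' `mn = L + 1` the node count of the shortest path. The distance is 0 for
#' a node and itself, 1/2 for adjacent nodes, approaches 1 for remote
#' nodes, and is defined as exactly 1 for disconnected pairs (the supremum
#' of the connected values, i.e. maximal dissimilarity). Always in [0, 1]
#' and symmetric.
#'
#' @param g a [social_graph()].
#' @param vi,vj node ids.
#' @return A number in \[0, 1\].
#' @export
node_distance <- function(g, vi, vj) {
  L <- shortest_path_edges(g, vi, vj)
  if (is.infinite(L)) 1 else L / (L + 1)
}

#' All-pairs normalized node distances
#'
#' The [node_distance()] values for every node pair, computed with a single
#' all-pairs breadth-first search. Used internally by the clustering
#' algorithm; exported because sweeps and audits also want it.
#'
#' @param g a [social_graph()].
#' @return A symmetric numeric matrix in \[0, 1\] with zero diagonal and
#'   node ids as dimnames.
#' @export
node_distance_matrix <- function(g) {
  L <- igraph::distances(as_igraph(g))
  D <- L / (L + 1)
  D[is.infinite(L)] <- 1
  dimnames(D) <- list(g$ids, g$ids)
  D
}

#' Distance from a node to a cluster
#'
#' The mean of [node_distance()] from `vi` to each member of the cluster
#' `s`. `vi` must not itself belong to `s`, and `s` must be non-empty.
#'
#' @param g a [social_graph()].
#' @param vi a node id outside `s`.
#' @param s character vector of node ids forming the cluster.
#' @return A number in \[0, 1\].
#' @export
structure_distance <- function(g, vi, s) {
  s <- as.character(s)
  if (length(s) == 0) stop_precondition("cluster s must be non-empty")
  if (as.character(vi) %in% s) {
    stop_precondition("node %s is a member of the cluster s", vi)
  }
  i <- check_ids(g, vi)
  js <- check_ids(g, s)
  L <- as.numeric(igraph::distances(as_igraph(g), v = i, to = js))
  d <- L / (L + 1)
  d[is.infinite(L)] <- 1
  mean(d)
}
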