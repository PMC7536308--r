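#' Time-based edge weights
#'
#' Weights each network edge by the mean time (days since first visit) of
#' the encounters in its shared row set, so a minimum spanning tree over
#' these weights is guided through temporally early connections first.
#'
#' @param graph a `mapper_graph`.
#' @param time numeric vector of per-row times (row-id order).
#' @return numeric vector, one weight per edge row.
#' @export
edge_time_weights <- function(graph, time) {
  if (length(time) < graph$n_rows) {
    stopf("edge_time_weights: need a time for every one of %d rows",
          graph$n_rows)
  }
  vapply(graph$edges$shared, function(s) mean(time[s]), numeric(1))
}

#' Node-index edge weights
#'
#' Weights an edge by the absolute difference of its endpoint ids. Node
#' ids are assigned in bin-traversal order, so for monotone lens functions
#' the index difference reflects topological proximity (benchmark mode).
#'
#' @param graph a `mapper_graph`.
#' @return numeric vector, one weight per edge row.
#' @export
index_weights <- function(graph) {
  abs(graph$edges$u - graph$edges$v)
}

# Kruskal spanning forest over an explicit edge list with fully
# deterministic tie-breaks: edges are taken in (weight, min id, max id)
# order. Returns the indices of the accepted edges.
kruskal_edges <- function(nn, u, v, w, early_stop_n = NULL) {
  ord <- order(w, pmin(u, v), pmax(u, v))
  parent <- seq_len(nn)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  picked <- integer(0)
  target <- if (is.null(early_stop_n)) nn - 1L else early_stop_n
  for (e in ord) {
    ru <- find(u[e]); rv <- find(v[e])
    if (ru != rv) {
      parent[ru] <- rv
      picked <- c(picked, e)
      if (length(picked) >= target) break
    }
  }
  sort(picked)
}

#' Minimum spanning forest of the network
#'
#' Kruskal's algorithm per connected component, with ties broken by
#' lexicographic `(weight, min id, max id)` edge order so the output is
#' deterministic. Each component contributes `|V_c| - 1` edges.
#'
#' @param graph a `mapper_graph`.
#' @param weights numeric per-edge weights (aligned with `graph$edges`).
#' @return an `mst_forest`: list with `edges` (data frame `u`, `v`,
#'   `weight`, `edge_index` into the parent graph), `n_nodes` and
#'   `total_weight`.
#' @export
minimum_spanning_tree <- function(graph, weights) {
  ed <- graph$edges
  if (nrow(ed) != length(weights)) {
    stopf("minimum_spanning_tree: %d weights for %d edges",
          length(weights), nrow(ed))
  }
  picked <- if (nrow(ed) == 0) integer(0) else
    kruskal_edges(n_nodes(graph), ed$u, ed$v, weights)
  tree <- structure(
    list(edges = data.frame(u = ed$u[picked], v = ed$v[picked],
                            weight = weights[picked], edge_index = picked),
         n_nodes = n_nodes(graph),
         total_weight = sum(weights[picked])),
    class = "mst_forest"
  )
  tree
}

#' @export
print.mst_forest <- function(x, ...) {
  cat(sprintf("mst_forest: %d nodes, %d tree edges, total weight %.3f\n",
              x$n_nodes, nrow(x$edges), x$total_weight))
  invisible(x)
}

# Adjacency list of a forest / edge list.
forest_adjacency <- function(nn, u, v) {
  adj <- rep(list(integer(0)), nn)
  for (e in seq_along(u)) {
    adj[[u[e]]] <- c(adj[[u[e]]], v[e])
    adj[[v[e]]] <- c(adj[[v[e]]], u[e])
  }
  adj
}

# Connected components of an edge list; returns membership vector.
edge_components <- function(nn, u, v) {
  parent <- seq_len(nn)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (e in seq_along(u)) {
    ru <- find(u[e]); rv <- find(v[e])
    if (ru != rv) parent[ru] <- rv
  }
  roots <- vapply(seq_len(nn), find, integer(1))
  match(roots, unique(roots))
}

# Unique path between two nodes of a tree (BFS parent pointers).
tree_path <- function(adj, from, to) {
  nn <- length(adj)
  parent <- rep(NA_integer_, nn)
  parent[from] <- from
  queue <- from
  while (length(queue) > 0 && is.na(parent[to])) {
    nxt <- integer(0)
    for (x in queue) {
      for (y in adj[[x]]) {
        if (is.na(parent[y])) {
          parent[y] <- x
          nxt <- c(nxt, y)
        }
      }
    }
    queue <- nxt
  }
  if (is.na(parent[to])) return(NULL)
  path <- to
  while (path[1] != from) path <- c(parent[path[1]], path)
  path
}
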