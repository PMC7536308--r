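#' Mapper configuration
#'
#' Parameters of the topological network construction.
#'
#' @param metric distance metric between encounters: `"cosine"` (clinical
#'   cohort mode) or `"euclidean"` (benchmark mode).
#' @param lens_pair `"svd+linf"` (first-singular-vector projection plus
#'   L-infinity centrality) or `"raw2d"` (the first two observed variables
#'   used directly, benchmark mode).
#' @param num_intervals resolution: number of cover intervals per lens
#'   dimension (the same in both dimensions).
#' @param gain overlap fraction between adjacent intervals, in (0, 1).
#' @param clusters_per_bin geometric scale of the within-bin clustering.
#'   In `"histogram"` mode (default) it is the resolution of the
#'   merge-height histogram whose first empty bin sets the dendrogram
#'   cutoff, so the cluster count adapts to each bin's density; in
#'   `"fixed_k"` mode the dendrogram is cut at exactly
#'   `min(clusters_per_bin, bin size)` clusters.
#' @param cluster_mode `"histogram"` or `"fixed_k"` (see
#'   `clusters_per_bin`).
#' @param random_seed integer, recorded for provenance.
#' @return a `mapper_config` list.
#' @export
mapper_config <- function(metric = c("cosine", "euclidean"),
                          lens_pair = c("svd+linf", "raw2d"),
                          num_intervals = 7, gain = 0.6,
                          clusters_per_bin = 8,
                          cluster_mode = c("histogram", "fixed_k"),
                          random_seed = 1L) {
  metric <- match.arg(metric)
  lens_pair <- match.arg(lens_pair)
  cluster_mode <- match.arg(cluster_mode)
  if (num_intervals < 1) stopf("mapper_config: num_intervals must be >= 1")
  if (gain <= 0 || gain >= 1) stopf("mapper_config: gain must be in (0, 1)")
  if (clusters_per_bin < 1) stopf("mapper_config: clusters_per_bin must be >= 1")
  structure(
    list(metric = metric, lens_pair = lens_pair,
         num_intervals = as.integer(num_intervals), gain = gain,
         clusters_per_bin = as.integer(clusters_per_bin),
         cluster_mode = cluster_mode,
         random_seed = as.integer(random_seed)),
    class = "mapper_config"
  )
}

#' Overlapping two-dimensional cover of the lens space
#'
#' Per lens dimension the range `R = max - min` is split into
#' `n = num_intervals` closed intervals of length `l = R / (n - (n-1) g)`
#' placed at step `s = l (1 - g)`, so adjacent intervals overlap by exactly
#' fraction `gain` of their length and their union is exactly the range.
#' The two-dimensional bins are the Cartesian product of the interval sets
#' (`n^2` bins); a row belongs to a bin iff both its lens values fall in
#' the bin's closed intervals, so every row is covered and boundary points
#' belong to all touching bins.
#'
#' @param lens two-column numeric matrix of lens values (one row per
#'   observation).
#' @param num_intervals intervals per dimension.
#' @param gain overlap fraction in (0, 1).
#' @return list of bins, each a list with `ix`, `iy` (interval indices),
#'   `x_range`, `y_range` and `members` (row ids); bins are ordered
#'   row-major (x outer, y inner).
#' @export
build_cover <- function(lens, num_intervals, gain) {
  lens <- as.matrix(lens)
  if (ncol(lens) != 2) stopf("build_cover: lens must have two columns")
  if (any(!is.finite(lens))) stopf("build_cover: lens values must be finite")
  n <- as.integer(num_intervals)
  if (is.na(n) || n < 1) stopf("build_cover: num_intervals must be >= 1")
  if (gain <= 0 || gain >= 1) stopf("build_cover: gain must be in (0, 1)")
  intervals_1d <- function(x) {
    lo <- min(x); hi <- max(x); R <- hi - lo
    len <- R / (n - (n - 1) * gain)
    step <- len * (1 - gain)
    lower <- lo + (seq_len(n) - 1) * step
    upper <- lower + len
    upper[n] <- hi  # guard against round-off shaving the top of the range
    cbind(lower, upper)
  }
  ix_int <- intervals_1d(lens[, 1])
  iy_int <- intervals_1d(lens[, 2])
  memb_1d <- function(x, ints) {
    lapply(seq_len(n), function(i) which(x >= ints[i, 1] & x <= ints[i, 2]))
  }
  mx <- memb_1d(lens[, 1], ix_int)
  my <- memb_1d(lens[, 2], iy_int)
  bins <- vector("list", n * n)
  b <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      b <- b + 1L
      bins[[b]] <- list(
        ix = i, iy = j,
        x_range = unname(ix_int[i, ]), y_range = unname(iy_int[j, ]),
        members = intersect(mx[[i]], my[[j]])
      )
    }
  }
  bins
}

#' Single-linkage clustering within one cover bin
#'
#' Builds a single-linkage agglomerative dendrogram over the bin's members
#' and cuts it in one of two ways. `"fixed_k"` cuts at exactly
#' `min(k, |members|)` clusters. `"histogram"` (the default used by
#' [build_mapper()]) chooses the cut height adaptively: the dendrogram
#' merge heights plus the bin diameter are histogrammed into `k` bins and
#' the cut is placed at the first empty histogram bin — the first gap in
#' the merge-height spectrum, separating within-cluster from
#' between-cluster linkage scales. When no gap exists the bin stays one
#' cluster, so sparse bins are not shattered into singletons and the
#' resulting network keeps its connectivity. Single linkage is the
#' canonical choice here because it merges along density ridges.
#'
#' @param members integer row ids in the bin.
#' @param D full pairwise distance matrix (subset internally), or `NULL`
#'   when `X` and `metric` are given instead.
#' @param k geometric scale: the cluster count in `"fixed_k"` mode, the
#'   histogram resolution in `"histogram"` mode.
#' @param X optional feature matrix used to compute bin-local distances
#'   when the full matrix is not materialised.
#' @param metric metric for bin-local distances when `X` is used.
#' @param mode `"fixed_k"` (default for direct calls) or `"histogram"`.
#' @return list of clusters (integer row-id vectors) partitioning
#'   `members`; an empty bin yields an empty list.
#' @export
cluster_bin <- function(members, D = NULL, k, X = NULL,
                        metric = c("cosine", "euclidean"),
                        mode = c("fixed_k", "histogram")) {
  mode <- match.arg(mode)
  m <- length(members)
  if (m == 0) return(list())
  if (m == 1) return(list(members))
  if (!is.null(D)) {
    dm <- as.dist(D[members, members, drop = FALSE])
  } else {
    metric <- match.arg(metric)
    Xm <- X[members, , drop = FALSE]
    dm <- if (metric == "euclidean") dist(Xm) else
      as.dist(pairwise_distance(Xm, "cosine"))
  }
  hc <- hclust(dm, method = "single")
  ct <- if (mode == "fixed_k") {
    cutree(hc, k = min(k, m))
  } else {
    cutoff <- height_histogram_cutoff(hc$height, max(dm), k)
    if (is.infinite(cutoff)) rep(1L, m) else cutree(hc, h = cutoff)
  }
  unname(lapply(split(members, ct), sort))
}

# First-empty-bin cutoff on the single-linkage merge-height spectrum:
# heights plus the diameter are histogrammed into `nb` bins; the cut sits
# at the midpoint of the first empty bin, Inf when there is no gap.
height_histogram_cutoff <- function(heights, diam, nb) {
  if (length(heights) == 0) return(Inf)
  if (diam - min(heights) < .Machine$double.eps) return(Inf)
  breaks <- seq(min(heights), diam, length.out = nb + 1)
  counts <- graphics::hist(c(heights, diam), breaks = breaks,
                           plot = FALSE)$counts
  gap <- which(counts == 0)
  if (length(gap) == 0) return(Inf)
  (breaks[gap[1]] + breaks[gap[1] + 1]) / 2
}

#' Assemble the Mapper network graph
#'
#' One node per within-bin cluster, with ids assigned consecutively in
#' (bin order, cluster order); two nodes are connected iff their member
#' sets intersect, and the edge carries the intersection as its shared set.
#' Clusters within one bin are disjoint, so edges only arise between bins.
#'
#' @param bin_clusters list (one entry per cover bin) of cluster lists as
#'   produced by [cluster_bin()].
#' @param n_rows total number of rows in the underlying table.
#' @return a `mapper_graph`: list with `nodes` (list of sorted row-id
#'   vectors), `node_bin` (originating bin index per node), `edges`
#'   (data frame `u`, `v` with list column `shared`), `attrs` (named list
#'   of per-node attribute vectors) and `n_rows`.
#' @export
build_mapper_graph <- function(bin_clusters, n_rows = NULL) {
  nodes <- list()
  node_bin <- integer(0)
  for (b in seq_along(bin_clusters)) {
    for (cl in bin_clusters[[b]]) {
      nodes[[length(nodes) + 1L]] <- sort(cl)
      node_bin <- c(node_bin, b)
    }
  }
  n_nodes <- length(nodes)
  if (is.null(n_rows)) {
    n_rows <- if (n_nodes > 0) max(unlist(nodes)) else 0L
  }
  # inverted index row -> containing nodes, then co-membership pairs
  row_ids <- unlist(nodes, use.names = FALSE)
  node_of <- rep.int(seq_len(n_nodes), lengths(nodes))
  edges <- data.frame(u = integer(0), v = integer(0))
  edges$shared <- list()
  if (length(row_ids) > 0) {
    by_row <- split(node_of, row_ids)
    pu <- integer(0); pv <- integer(0); pr <- integer(0)
    for (r in names(by_row)) {
      ns <- sort(by_row[[r]])
      if (length(ns) >= 2) {
        pairs <- combn(ns, 2)
        pu <- c(pu, pairs[1, ]); pv <- c(pv, pairs[2, ])
        pr <- c(pr, rep.int(as.integer(r), ncol(pairs)))
      }
    }
    if (length(pu) > 0) {
      key <- paste(pu, pv, sep = "-")
      shared <- lapply(split(pr, key), sort)
      uk <- unique(key)
      um <- do.call(rbind, strsplit(uk, "-", fixed = TRUE))
      eu <- as.integer(um[, 1]); ev <- as.integer(um[, 2])
      ord <- order(eu, ev)
      edges <- data.frame(u = eu[ord], v = ev[ord])
      edges$shared <- unname(shared[uk[ord]])
    }
  }
  structure(
    list(nodes = lapply(nodes, as.integer), node_bin = node_bin,
         edges = edges, attrs = list(), n_rows = as.integer(n_rows)),
    class = "mapper_graph"
  )
}

#' Number of nodes in a mapper graph
#' @param graph a `mapper_graph`.
#' @return integer node count.
#' @export
n_nodes <- function(graph) length(graph$nodes)

#' Member rows of one node
#' @param graph a `mapper_graph`.
#' @param id node id.
#' @return sorted integer vector of row ids.
#' @export
node_members <- function(graph, id) graph$nodes[[id]]

#' @export
print.mapper_graph <- function(x, ...) {
  cat(sprintf("mapper_graph: %d nodes, %d edges over %d rows\n",
              n_nodes(x), nrow(x$edges), x$n_rows))
  if (length(x$attrs) > 0) {
    cat("  node attributes:", paste(names(x$attrs), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Attach a per-node summary attribute
#'
#' Aggregates a per-row value over each node's members: `mean` for
#' continuous enrichment (e.g. mean time since first visit) or `majority`
#' for categorical enrichment (e.g. most frequent hidden state), with ties
#' broken toward the smallest value.
#'
#' @param graph a `mapper_graph`.
#' @param values numeric vector with one value per table row.
#' @param agg `"mean"` or `"majority"`.
#' @param name attribute name under which to store the result; defaults to
#'   `"mean_<agg>"`-style names `mean_value` / `majority_value`.
#' @return the graph with `attrs[[name]]` filled (one entry per node).
#' @export
enrich_nodes <- function(graph, values, agg = c("mean", "majority"),
                         name = NULL) {
  agg <- match.arg(agg)
  if (length(values) < graph$n_rows) {
    stopf("enrich_nodes: need a value for every one of %d rows", graph$n_rows)
  }
  if (is.null(name)) name <- paste0(agg, "_value")
  f <- if (agg == "mean") {
    function(m) mean(values[m])
  } else {
    function(m) {
      tab <- table(values[m])
      cand <- as.numeric(names(tab)[tab == max(tab)])
      min(cand)
    }
  }
  graph$attrs[[name]] <- vapply(graph$nodes, f, numeric(1))
  graph
}

#' Build the full Mapper network from a feature matrix
#'
#' Runs the complete construction: distance matrix (when the lens pair
#' needs it), lens computation, overlapping cover, per-bin single-linkage
#' clustering and graph assembly. In `raw2d` mode the global distance
#' matrix is never materialised; bin-local distances are computed on the
#' fly, which keeps large benchmark runs cheap.
#'
#' @param X numeric feature matrix (rows = observations in row-id order).
#' @param config a [mapper_config()].
#' @param D optional precomputed distance matrix (reused for the
#'   centrality lens and bin clustering).
#' @return a `mapper_graph` with the `config`, lens values and (when
#'   materialised) distance matrix attached as `config`, `lens`, `D`.
#' @export
build_mapper <- function(X, config = mapper_config(), D = NULL) {
  X <- as.matrix(X)
  if (config$lens_pair == "svd+linf") {
    if (is.null(D)) D <- pairwise_distance(X, config$metric)
    lens <- cbind(lens_svd(X), lens_linf_centrality(D))
  } else {
    if (ncol(X) < 2) stopf("build_mapper: raw2d lens needs >= 2 columns")
    lens <- X[, 1:2, drop = FALSE]
  }
  cover <- build_cover(lens, config$num_intervals, config$gain)
  bin_clusters <- lapply(cover, function(bin) {
    cluster_bin(bin$members, D = D, k = config$clusters_per_bin,
                X = X, metric = config$metric, mode = config$cluster_mode)
  })
  graph <- build_mapper_graph(bin_clusters, n_rows = nrow(X))
  graph$config <- config
  graph$lens <- lens
  graph$D <- D
  pt_log("mapper", sprintf(
    "metric=%s lens=%s intervals=%d gain=%.2f clusters_per_bin=%d -> %d nodes, %d edges",
    config$metric, config$lens_pair, config$num_intervals, config$gain,
    config$clusters_per_bin, n_nodes(graph), nrow(graph$edges)))
  graph
}

#' Read a mapper graph from its JSON export
#'
#' Inverse of [write_mapper_json()]; restores nodes, edges, shared sets
#' and per-node attributes.
#'
#' @param path file written by [write_mapper_json()].
#' @param n_rows optional row count of the underlying table (defaults to
#'   the largest member id seen).
#' @return a `mapper_graph`.
#' @export
read_mapper_json <- function(path, n_rows = NULL) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  nodes <- lapply(obj$nodes, function(nd) sort(as.integer(unlist(nd$members))))
  attr_names <- unique(unlist(lapply(obj$nodes, function(nd) names(nd$attrs))))
  attrs <- lapply(attr_names, function(an) {
    vapply(obj$nodes, function(nd) as.numeric(nd$attrs[[an]]), numeric(1))
  })
  names(attrs) <- attr_names
  edges <- data.frame(
    u = vapply(obj$edges, function(e) as.integer(e$u), integer(1)),
    v = vapply(obj$edges, function(e) as.integer(e$v), integer(1))
  )
  edges$shared <- lapply(obj$edges, function(e) sort(as.integer(unlist(e$shared))))
  if (is.null(n_rows)) {
    n_rows <- if (length(nodes) > 0) max(unlist(nodes)) else 0L
  }
  structure(
    list(nodes = nodes, node_bin = rep(NA_integer_, length(nodes)),
         edges = edges, attrs = attrs, n_rows = as.integer(n_rows)),
    class = "mapper_graph"
  )
}

#' Convert a mapper graph to an igraph object
#'
#' Vertices carry the node id, member count and any enrichment attributes;
#' edges carry the shared-set size and optional weights.
#'
#' @param graph a `mapper_graph`.
#' @param weights optional numeric edge weights (one per edge row).
#' @return an undirected `igraph` graph.
#' @export
mapper_to_igraph <- function(graph, weights = NULL) {
  g <- igraph::make_empty_graph(n = n_nodes(graph), directed = FALSE)
  igraph::V(g)$name <- as.character(seq_len(n_nodes(graph)))
  igraph::V(g)$size <- lengths(graph$nodes)
  for (an in names(graph$attrs)) {
    g <- igraph::set_vertex_attr(g, an, value = graph$attrs[[an]])
  }
  if (nrow(graph$edges) > 0) {
    g <- igraph::add_edges(g, rbind(graph$edges$u, graph$edges$v))
    igraph::E(g)$shared_size <- lengths(graph$edges$shared)
    if (!is.null(weights)) igraph::E(g)$weight <- weights
  }
  g
}

#' Export a mapper graph to GraphML
#' @param graph a `mapper_graph`.
#' @param path output file path.
#' @param weights optional per-edge weights exported as `weight`.
#' @return invisibly, `path`.
#' @export
write_mapper_graphml <- function(graph, path, weights = NULL) {
  igraph::write_graph(mapper_to_igraph(graph, weights), path,
                      format = "graphml")
  invisible(path)
}

#' Export a mapper graph to JSON
#'
#' Dialect: `{nodes: [{id, members, attrs}], edges: [{u, v, shared}]}`,
#' with member lists sorted ascending so exports diff cleanly.
#'
#' @param graph a `mapper_graph`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_mapper_json <- function(graph, path) {
  nodes <- lapply(seq_len(n_nodes(graph)), function(i) {
    at <- lapply(graph$attrs, function(a) a[[i]])
    list(id = i, members = sort(graph$nodes[[i]]),
         attrs = if (length(at)) at else setNames(list(), character(0)))
  })
  edges <- lapply(seq_len(nrow(graph$edges)), function(e) {
    list(u = graph$edges$u[e], v = graph$edges$v[e],
         shared = sort(graph$edges$shared[[e]]))
  })
  jsonlite::write_json(list(nodes = nodes, edges = edges), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
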