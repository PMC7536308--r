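#' Trajectory object
#'
#' An ordered sequence of network node ids. Mined trajectories are
#' root-to-leaf paths of the time-guided spanning tree; individual
#' trajectories are the compressed node sequences of single subjects.
#'
#' @param node_ids ordered integer vector of node ids (non-empty).
#' @param kind `"mined"` or `"individual"`.
#' @param terminal_community optional community id of the final node.
#' @param subject optional subject id (individual trajectories).
#' @return a `trajectory` object.
#' @export
trajectory <- function(node_ids, kind = c("mined", "individual"),
                       terminal_community = NA_integer_, subject = NULL) {
  kind <- match.arg(kind)
  if (length(node_ids) == 0) stopf("trajectory: node_ids must be non-empty")
  structure(
    list(node_ids = as.integer(node_ids), kind = kind,
         terminal_community = terminal_community, subject = subject),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("%s trajectory%s: <%s>%s\n", x$kind,
              if (!is.null(x$subject)) paste0(" [", x$subject, "]") else "",
              paste(x$node_ids, collapse = ", "),
              if (!is.na(x$terminal_community))
                paste0(" (terminal community ", x$terminal_community, ")")
              else ""))
  invisible(x)
}

#' Mine trajectories from the spanning tree
#'
#' By default the tree is rooted at the node with the smallest mean time
#' since first visit (ties toward the lowest node id) — the node holding
#' the earliest observations, from which all progression pathways
#' radiate. Each leaf defines one mined trajectory: the unique
#' root-to-leaf path. When the forest has several components the largest
#' one is used (logged). [mine_trajectories()] builds on this with
#' progression-aware root and terminal rules.
#'
#' @param tree an `mst_forest` from [minimum_spanning_tree()].
#' @param mean_time per-node mean time attribute (e.g.
#'   `graph$attrs$mean_time`).
#' @param partition optional `community_partition` used to fill each
#'   trajectory's `terminal_community`.
#' @param root optional node id to root at, overriding the minimal
#'   mean-time rule (the component containing it is then used).
#' @param leaves optional candidate set of terminal node ids; only tree
#'   leaves in this set yield trajectories. `NULL` keeps every leaf.
#' @return list of mined `trajectory` objects, sorted by terminal node id.
#' @export
extract_trajectories <- function(tree, mean_time, partition = NULL,
                                 root = NULL, leaves = NULL) {
  nn <- tree$n_nodes
  comp <- edge_components(nn, tree$edges$u, tree$edges$v)
  sizes <- tabulate(comp)
  if (length(unique(comp)) > 1) {
    pt_log("trajectories", sprintf(
      "forest has %d components; using %s",
      length(unique(comp)),
      if (is.null(root)) sprintf("the largest (%d nodes)", max(sizes))
      else "the root's component"))
  }
  if (is.null(root)) {
    nodes_in <- which(comp == which.max(sizes))
    root <- nodes_in[order(mean_time[nodes_in], nodes_in)[1]]
  } else {
    nodes_in <- which(comp == comp[root])
  }
  if (length(nodes_in) == 1) {
    tr <- trajectory(root, "mined",
                     terminal_community = terminal_comm(partition, root))
    return(list(tr))
  }
  keep <- tree$edges$u %in% nodes_in  # tree edges of the main component
  adj <- forest_adjacency(nn, tree$edges$u[keep], tree$edges$v[keep])
  degs <- lengths(adj)
  term <- setdiff(nodes_in[degs[nodes_in] == 1], root)
  if (!is.null(leaves)) term <- intersect(term, leaves)
  term <- sort(term)
  lapply(term, function(leaf) {
    trajectory(tree_path(adj, root, leaf), "mined",
               terminal_community = terminal_comm(partition, leaf))
  })
}

#' Mine progression trajectories from a network
#'
#' The full trajectory-mining step: weight the edges (by mean encounter
#' time, or by node-index distance in benchmark mode), take the minimum
#' spanning tree, root it and read off the progression pathways. Two
#' rules make the automatic branch reading robust:
#'
#' * *Root*: the node holding the largest number of first observations
#'   (each subject's or sequence's earliest encounter) — the cluster
#'   where follow-up starts (ties: smaller mean time, then lower id).
#' * *Termini*: a tree leaf counts as a progression endpoint only if its
#'   mean time exceeds the component's average node mean time (an
#'   endpoint is late, not an early side-pocket of the starting region)
#'   and it holds at least `min_share` of all observations (a phenotype
#'   is not supported by a couple of stray encounters). If no leaf
#'   qualifies, all leaves are kept (with a warning).
#'
#' @param graph a `mapper_graph` with a `mean_time` attribute (see
#'   [enrich_nodes()]).
#' @param time per-row time values (used for `"time"` edge weights).
#' @param first logical per-row vector marking each subject's or
#'   sequence's first observation.
#' @param weights `"time"` (clinical cohort mode) or `"index"`
#'   (benchmark mode).
#' @param partition optional `community_partition` for
#'   `terminal_community`.
#' @param min_share minimum fraction of all observations a terminal node
#'   must hold (default 0.005).
#' @return list of mined `trajectory` objects, sorted by terminal node
#'   id, with the spanning tree attached as attribute `tree`.
#' @export
mine_trajectories <- function(graph, time, first, weights = c("time", "index"),
                              partition = NULL, min_share = 0.005) {
  weights <- match.arg(weights)
  if (is.null(graph$attrs$mean_time)) {
    graph <- enrich_nodes(graph, time, "mean", name = "mean_time")
  }
  mt <- graph$attrs$mean_time
  w <- if (weights == "time") edge_time_weights(graph, time) else
    index_weights(graph)
  tree <- minimum_spanning_tree(graph, w)
  n_first <- vapply(graph$nodes, function(m) sum(first[m]), numeric(1))
  root <- order(-n_first, mt, seq_len(n_nodes(graph)))[1]
  comp <- edge_components(tree$n_nodes, tree$edges$u, tree$edges$v)
  nodes_in <- which(comp == comp[root])
  min_size <- max(2, ceiling(min_share * graph$n_rows))
  late <- which(mt > mean(mt[nodes_in]) & lengths(graph$nodes) >= min_size)
  out <- extract_trajectories(tree, mt, partition, root = root,
                              leaves = late)
  if (length(out) == 0) {
    warning("mine_trajectories: no leaf qualifies as a progression endpoint; keeping all leaves")
    out <- extract_trajectories(tree, mt, partition, root = root)
  }
  attr(out, "tree") <- tree
  attr(out, "root") <- root
  out
}

terminal_comm <- function(partition, node) {
  if (is.null(partition)) NA_integer_ else
    as.integer(partition$membership[node])
}

#' Jaccard similarity of two trajectories
#'
#' Set Jaccard on node ids: `|A cap B| / |A cup B|`. Order and
#' multiplicity are ignored — a subject revisiting a node contributes it
#' once.
#'
#' @param A,B `trajectory` objects or plain node-id vectors (non-empty).
#' @return similarity in `[0, 1]`; 1 iff equal as sets.
#' @export
jaccard_similarity <- function(A, B) {
  a <- unique(if (inherits(A, "trajectory")) A$node_ids else A)
  b <- unique(if (inherits(B, "trajectory")) B$node_ids else B)
  if (length(a) == 0 || length(b) == 0) {
    stopf("jaccard_similarity: trajectories must be non-empty")
  }
  length(intersect(a, b)) / length(union(a, b))
}

#' Individual trajectories: map encounters to network nodes
#'
#' Cover bins overlap, so one encounter can sit in several nodes; it is
#' resolved to the single containing node whose other members are on
#' average closest to it (a node containing only the encounter itself
#' counts as distance 0; ties go to the lowest node id). Per subject the
#' resolved nodes are ordered by encounter time and collapsed with
#' [compress_sequence()].
#'
#' @param graph a `mapper_graph`.
#' @param table the `observation_table` the graph was built on.
#' @param D full pairwise distance matrix over the table's rows.
#' @return named list (by subject id) of individual `trajectory` objects;
#'   encounters covered by no node are dropped with a warning.
#' @export
map_observations_to_nodes <- function(graph, table, D) {
  nn <- n_nodes(graph)
  n_rows <- graph$n_rows
  row_nodes <- rep(list(integer(0)), n_rows)
  for (i in seq_len(nn)) {
    for (r in graph$nodes[[i]]) row_nodes[[r]] <- c(row_nodes[[r]], i)
  }
  assigned <- rep(NA_integer_, n_rows)
  for (r in seq_len(n_rows)) {
    cand <- row_nodes[[r]]
    if (length(cand) == 0) next
    if (length(cand) == 1) {
      assigned[r] <- cand
    } else {
      md <- vapply(cand, function(i) {
        others <- setdiff(graph$nodes[[i]], r)
        if (length(others) == 0) 0 else mean(D[r, others])
      }, numeric(1))
      assigned[r] <- cand[order(md, cand)[1]]
    }
  }
  uncovered <- sum(is.na(assigned))
  if (uncovered > 0) {
    warning(sprintf("map_observations_to_nodes: %d encounter(s) covered by no node; dropped",
                    uncovered))
  }
  keep <- which(!is.na(assigned))
  ord <- keep[order(table$subject_id[keep], table$time_days[keep], keep)]
  by_subject <- split(assigned[ord], table$subject_id[ord])
  out <- lapply(names(by_subject), function(s) {
    trajectory(compress_sequence(by_subject[[s]]), "individual", subject = s)
  })
  names(out) <- names(by_subject)
  out
}

#' Assign subjects to mined trajectories
#'
#' Each individual trajectory is compared with every mined trajectory by
#' Jaccard similarity and assigned to the best-matching one (ties toward
#' the lowest mined-trajectory index).
#'
#' @param individuals list of individual `trajectory` objects (e.g. from
#'   [map_observations_to_nodes()]).
#' @param mined non-empty list of mined `trajectory` objects.
#' @return data frame with columns `subject`, `trajectory_id` (index into
#'   `mined`) and `jaccard`.
#' @export
assign_subjects <- function(individuals, mined) {
  if (length(mined) == 0) stopf("assign_subjects: no mined trajectories")
  res <- lapply(seq_along(individuals), function(i) {
    sims <- vapply(mined, jaccard_similarity, numeric(1), B = individuals[[i]])
    best <- which_max_first(sims)
    subj <- individuals[[i]]$subject
    data.frame(
      subject = if (is.null(subj)) as.character(i) else as.character(subj),
      trajectory_id = best, jaccard = sims[best],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, res)
}

#' Export mined trajectories and subject assignments
#'
#' Writes `{trajectories: [{id, nodes, terminal_community}],
#' assignments: [{subject, trajectory_id, jaccard}]}` as JSON, and the
#' assignments as a flat CSV when `csv_path` is given.
#'
#' @param mined list of mined `trajectory` objects.
#' @param assignments assignment data frame from [assign_subjects()]
#'   (optional).
#' @param path JSON output path.
#' @param csv_path optional CSV output path for the assignments.
#' @return invisibly, `path`.
#' @export
write_trajectories_json <- function(mined, assignments = NULL, path,
                                    csv_path = NULL) {
  tr <- lapply(seq_along(mined), function(i) {
    tc <- mined[[i]]$terminal_community
    list(id = i, nodes = mined[[i]]$node_ids,
         terminal_community = if (is.na(tc)) NULL else tc)
  })
  obj <- list(trajectories = tr)
  if (!is.null(assignments)) obj$assignments <- assignments
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(assignments) && !is.null(csv_path)) {
    write.csv(assignments, csv_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
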