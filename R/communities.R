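#' Unweighted Newman-Girvan modularity of a partition
#'
#' `Q = sum_c (e_c / m - (d_c / 2m)^2)` where `e_c` is the number of edges
#' inside community `c`, `d_c` the sum of its members' degrees and `m` the
#' total edge count. By convention `Q = 0` for an edgeless graph.
#'
#' @param graph a `mapper_graph` (or any list with an `edges` data frame of
#'   `u`, `v` columns and a node count reachable via [n_nodes()]).
#' @param membership integer community id per node.
#' @return the modularity score.
#' @export
modularity_q <- function(graph, membership) {
  u <- graph$edges$u; v <- graph$edges$v
  m <- length(u)
  if (m == 0) return(0)
  nn <- n_nodes(graph)
  deg <- tabulate(c(u, v), nbins = nn)
  comm <- sort(unique(membership))
  e_c <- vapply(comm, function(cc) sum(membership[u] == cc & membership[v] == cc),
                numeric(1))
  d_c <- vapply(comm, function(cc) sum(deg[membership == cc]), numeric(1))
  sum(e_c / m - (d_c / (2 * m))^2)
}

# Greedy modularity maximisation: agglomerative merges alternated with
# single-node local moves (including splits to a fresh singleton) until a
# combined fixed point, repeated from one deterministic and several
# seeded random starts; the best partition wins. Deterministic given the
# input: the internal seed is fixed and the caller's RNG is untouched.
greedy_modularity_membership <- function(nn, u, v, n_starts = NULL,
                                         seed = 42L) {
  m <- length(u)
  deg <- tabulate(c(u, v), nbins = nn)
  adj <- forest_adjacency(nn, u, v)
  if (is.null(n_starts)) {
    n_starts <- if (nn <= 50) 100L else max(10L, ceiling(5000 / nn))
  }
  qof <- function(memb) {
    d_c <- numeric(nn)
    agg <- tapply(deg, memb, sum)
    d_c[as.integer(names(agg))] <- agg
    sum(memb[u] == memb[v]) / m - sum((d_c / (2 * m))^2)
  }
  local_moves <- function(memb, ord_fun) {
    d_c <- numeric(nn)
    agg <- tapply(deg, memb, sum)
    d_c[as.integer(names(agg))] <- agg
    n_c <- tabulate(memb, nn)
    for (pass in seq_len(100)) {
      moved <- FALSE
      for (i in ord_fun()) {
        nb <- adj[[i]]
        if (length(nb) == 0) next
        a <- memb[i]
        cand <- unique(memb[nb])
        cand <- cand[cand != a]
        if (n_c[a] > 1) {
          free <- which(n_c == 0)
          if (length(free) > 0) cand <- c(cand, free[1])
        }
        if (length(cand) == 0) next
        e_ia <- sum(memb[nb] == a)
        dq <- vapply(cand, function(bb) {
          (sum(memb[nb] == bb) - e_ia) / m -
            deg[i] * (d_c[bb] - d_c[a] + deg[i]) / (2 * m^2)
        }, numeric(1))
        best <- order(-dq, cand)[1]
        if (dq[best] > 1e-12) {
          bb <- cand[best]
          d_c[a] <- d_c[a] - deg[i]; d_c[bb] <- d_c[bb] + deg[i]
          n_c[a] <- n_c[a] - 1L; n_c[bb] <- n_c[bb] + 1L
          memb[i] <- bb
          moved <- TRUE
        }
      }
      if (!moved) break
    }
    memb
  }
  merges <- function(memb) {
    repeat {
      a <- pmin(memb[u], memb[v]); b <- pmax(memb[u], memb[v])
      inter <- a != b
      if (!any(inter)) break
      key <- paste(a[inter], b[inter], sep = "-")
      e_ab <- table(key)
      d_c <- numeric(nn)
      agg <- tapply(deg, memb, sum)
      d_c[as.integer(names(agg))] <- agg
      pk <- do.call(rbind, strsplit(names(e_ab), "-", fixed = TRUE))
      pa <- as.integer(pk[, 1]); pb <- as.integer(pk[, 2])
      dq <- as.numeric(e_ab) / m - d_c[pa] * d_c[pb] / (2 * m^2)
      best <- order(-dq, pa, pb)[1]
      if (dq[best] <= 1e-12) break
      memb[memb == pb[best]] <- pa[best]
    }
    memb
  }
  refine <- function(memb, ord_fun) {
    for (round in seq_len(20)) {
      old <- match(memb, unique(memb))
      memb <- local_moves(merges(memb), ord_fun)
      if (identical(match(memb, unique(memb)), old)) break
    }
    memb
  }
  best_memb <- refine(seq_len(nn), function() seq_len(nn))
  best_q <- qof(best_memb)
  with_local_seed(seed, {
    for (r in seq_len(n_starts)) {
      init <- sample.int(max(2L, sample.int(nn, 1)), nn, replace = TRUE)
      memb <- refine(init, function() sample.int(nn))
      q <- qof(memb)
      if (q > best_q + 1e-12) {
        best_q <- q
        best_memb <- memb
      }
    }
  })
  match(best_memb, unique(best_memb))  # relabel by first appearance
}

#' Community structure by modularity maximisation
#'
#' Partitions the network into communities by maximising unweighted
#' modularity. Graphs with at most `exact_max_nodes` nodes are solved to
#' the global optimum (integer-programming formulation); larger graphs use
#' a deterministic greedy agglomeration with single-node refinement and the
#' result is flagged approximate. An edgeless graph yields one community
#' per node with `Q = 0`.
#'
#' @param graph a `mapper_graph`.
#' @param exact_max_nodes largest size solved exactly (default 16).
#' @param method `"auto"` (size-based), `"exact"` or `"greedy"`.
#' @return a `community_partition`: list with `membership` (community id
#'   per node), `modularity`, `method` and `approximate` flag.
#' @export
optimal_communities <- function(graph, exact_max_nodes = 16,
                                method = c("auto", "exact", "greedy")) {
  method <- match.arg(method)
  nn <- n_nodes(graph)
  if (nn == 0) stopf("optimal_communities: empty graph")
  if (nrow(graph$edges) == 0) {
    warning("optimal_communities: graph has no edges; every node is its own community")
    part <- list(membership = seq_len(nn), modularity = 0,
                 method = "singletons", approximate = FALSE)
    class(part) <- "community_partition"
    return(part)
  }
  if (method == "auto") {
    method <- if (nn <= exact_max_nodes) "exact" else "greedy"
  }
  if (method == "exact") {
    ig <- mapper_to_igraph(graph)
    memb <- as.integer(igraph::membership(
      igraph::cluster_optimal(ig, weights = NA)))
    approx <- FALSE
  } else {
    memb <- greedy_modularity_membership(nn, graph$edges$u, graph$edges$v)
    approx <- TRUE
    pt_log("communities", "greedy modularity search; partition is approximate")
  }
  part <- list(membership = memb, modularity = modularity_q(graph, memb),
               method = method, approximate = approx)
  class(part) <- "community_partition"
  part
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("community_partition: %d communities, Q = %.4f (%s%s)\n",
              length(unique(x$membership)), x$modularity, x$method,
              if (x$approximate) ", approximate" else ""))
  invisible(x)
}
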